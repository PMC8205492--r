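# self-consistent variant records: p is the two-sided normal p of beta/se
make_records <- function(n = 20, seed = 1, chrom = "1", spacing = 10000) {
  set.seed(seed)
  se <- runif(n, 0.01, 0.1)
  z <- rnorm(n)
  beta <- z * se
  tibble::tibble(
    chrom = chrom,
    pos = 1 + (seq_len(n) - 1) * spacing,
    ref = "A", alt = "B",
    eaf = runif(n, 0.05, 0.95),
    beta = beta, se = se,
    p = 2 * pnorm(-abs(z)),
    n = 10000, info = runif(n, 0.9, 1))
}

make_ss <- function(n = 20, seed = 1, ...) {
  as_sumstats(make_records(n, seed, ...), trait_id = "t", trait_type = "quantitative")
}

# records engineered so 2*n*f*(1-f) = sigma^2 / V exactly
make_sdy_records <- function(sigma, n_var = 50, n = 10000, seed = 3) {
  set.seed(seed)
  eaf <- runif(n_var, 0.05, 0.5)
  V <- sigma^2 / (2 * n * eaf * (1 - eaf))
  z <- rnorm(n_var)
  tibble::tibble(chrom = "1", pos = seq_len(n_var) * 1000, ref = "A", alt = "B",
                 eaf = eaf, beta = z * sqrt(V), se = sqrt(V),
                 p = 2 * pnorm(-abs(z)), n = n, info = 1)
}

# record columns only, stripped of provenance attributes, for equality checks
records_of <- function(ss) {
  df <- as.data.frame(ss)
  attributes(df) <- attributes(df)[c("names", "row.names")]
  class(df) <- "data.frame"
  rownames(df) <- NULL
  df
}

# brute-force two-pass Pearson correlation
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# numerically integrated Wakefield Bayes factor (quadrature oracle)
abf_quadrature <- function(beta, V, omega) {
  num <- stats::integrate(function(b) dnorm(beta, b, sqrt(V)) * dnorm(b, 0, sqrt(omega)),
                          lower = -Inf, upper = Inf, rel.tol = 1e-12)$value
  num / dnorm(beta, 0, sqrt(V))
}

# copula-implied genotype correlation between two thresholded AR(1) neighbours
orthant_genotype_r <- function(rho, maf1, maf2) {
  q1 <- qnorm(maf1); q2 <- qnorm(maf2)
  p11 <- stats::integrate(function(z) dnorm(z) * pnorm((q2 - rho * z) / sqrt(1 - rho^2)),
                          lower = -Inf, upper = q1, rel.tol = 1e-10)$value
  (p11 - maf1 * maf2) / sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}
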