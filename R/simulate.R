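#' Configuration for a synthetic GWAS
#'
#' Describes the genotype law (LD blocks, minor-allele-frequency spectrum),
#' the trait architecture (causal variants with per-variant variance
#' explained, quantitative or liability-threshold binary), and the seed that
#' fully determines every draw.
#'
#' @param n_samples Number of individuals.
#' @param n_variants Number of variants.
#' @param blocks Data frame with columns `length` and `rho`: consecutive LD
#'   blocks and the latent AR(1) neighbour correlation inside each. Block
#'   lengths must sum to `n_variants`. Default: one block with `rho = 0`
#'   (linkage equilibrium).
#' @param maf_range Bounds of the uniform MAF spectrum (default U(0.01, 0.5)).
#' @param causal Data frame with columns `index` (variant column) and `ve`
#'   (fraction of trait variance explained); `NULL` for a null trait. Total
#'   `ve` must not exceed 1.
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param prevalence Case fraction for binary traits (liability threshold).
#' @param pos_spacing Physical spacing between adjacent variants in bp
#'   (default 2,000, so a 500-variant panel spans 1 Mb on one chromosome).
#' @param chrom Chromosome label for the simulated variants.
#' @param seed Integer seed; mandatory.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples, n_variants, blocks = NULL,
                       maf_range = c(0.01, 0.5), causal = NULL,
                       trait_type = c("quantitative", "case_control"),
                       prevalence = 0.1, pos_spacing = 2000L, chrom = "1",
                       seed) {
  trait_type <- match.arg(trait_type)
  if (missing(seed)) abort("sim_config requires an explicit seed")
  if (is.null(blocks)) blocks <- tibble(length = n_variants, rho = 0)
  blocks <- as_tibble(blocks)
  if (sum(blocks$length) != n_variants) {
    abort("block lengths must sum to n_variants")
  }
  stopifnot(all(blocks$rho >= 0), all(blocks$rho < 1))
  if (!is.null(causal)) {
    causal <- as_tibble(causal)
    stopifnot(all(causal$index >= 1), all(causal$index <= n_variants))
    if (sum(causal$ve) > 1) abort("total variance explained exceeds 1")
  }
  if (trait_type == "case_control") stopifnot(prevalence > 0, prevalence < 1)
  structure(list(n_samples = n_samples, n_variants = n_variants,
                 blocks = blocks, maf_range = maf_range, causal = causal,
                 trait_type = trait_type, prevalence = prevalence,
                 pos_spacing = as.integer(pos_spacing), chrom = chrom,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# MAF spectrum is drawn from config$seed so paired studies on the same
# genotype law share variant frequencies while drawing fresh individuals
sim_mafs <- function(config) {
  withr_seed(config$seed,
             runif(config$n_variants, config$maf_range[1], config$maf_range[2]))
}

#' Simulate LD-structured genotype dosages
#'
#' Genotypes arise from a Gaussian copula: per haplotype and per block, a
#' latent AR(1) Gaussian series with neighbour correlation `rho` is
#' thresholded at the MAF-matching normal quantile to a 0/1 allele; two
#' independent haplotypes sum to a dosage in \{0,1,2\}. Blocks with `rho = 0`
#' draw dosages directly as Binomial(2, maf). Draw order (after the MAF
#' spectrum, which always comes from `config$seed`): blocks left to right, two
#' haplotype latent matrices per block, column-major.
#'
#' @param config A [sim_config()].
#' @param seed Seed for the haplotype draws; default `config$seed + 1` so the
#'   same genotype law can be realised for independent sample sets by varying
#'   this argument.
#' @return An [ld_panel()] with variant positions
#'   `1, 1 + spacing, 1 + 2*spacing, ...` on `config$chrom`.
#' @export
simulate_genotypes <- function(config, seed = config$seed + 1L) {
  mafs <- sim_mafs(config)
  n <- config$n_samples
  withr_seed(seed, {
    cols <- vector("list", nrow(config$blocks))
    off <- 0L
    for (b in seq_len(nrow(config$blocks))) {
      len <- config$blocks$length[b]
      rho <- config$blocks$rho[b]
      maf_b <- mafs[off + seq_len(len)]
      if (rho == 0) {
        g <- matrix(rbinom(n * len, 2L, rep(maf_b, each = n)), nrow = n)
      } else {
        g <- matrix(0L, n, len)
        for (h in 1:2) {
          lat <- matrix(rnorm(n * len), n, len)
          s <- sqrt(1 - rho^2)
          for (j in 2:len) lat[, j] <- rho * lat[, j - 1] + s * lat[, j]
          g <- g + (lat < matrix(qnorm(maf_b), n, len, byrow = TRUE))
        }
      }
      cols[[b]] <- g
      off <- off + len
    }
    dos <- do.call(cbind, cols)
  })
  m <- config$n_variants
  variants <- tibble(chrom = config$chrom,
                     pos = 1 + (seq_len(m) - 1) * config$pos_spacing,
                     ref = "A", alt = "B", target_maf = mafs)
  ld_panel(dos, variants)
}

#' Simulate a trait on a genotype panel
#'
#' Quantitative: `y = sum_k beta_k * scale(g_k) + e`, `e ~ N(0, 1 - h2)` with
#' `beta_k = sqrt(ve_k)`, so trait variance is approximately 1. Binary: the
#' same construction is the liability; an individual is a case iff liability
#' exceeds the normal quantile of `1 - prevalence`.
#'
#' @param panel An [ld_panel()] from [simulate_genotypes()].
#' @param config The matching [sim_config()].
#' @param seed Seed for the environmental noise; default `config$seed + 2`.
#' @return Numeric phenotype vector (0/1 for binary traits).
#' @export
simulate_trait <- function(panel, config, seed = config$seed + 2L) {
  n <- nrow(panel$dosages)
  h2 <- if (is.null(config$causal)) 0 else sum(config$causal$ve)
  if (h2 > 1) abort("total variance explained exceeds 1")
  genet <- numeric(n)
  if (!is.null(config$causal)) {
    for (k in seq_len(nrow(config$causal))) {
      g <- panel$dosages[, config$causal$index[k]]
      sg <- stats::sd(g)
      if (sg == 0) abort("causal variant is monomorphic in this realisation")
      genet <- genet + sqrt(config$causal$ve[k]) * (g - mean(g)) / sg
    }
  }
  y <- genet + withr_seed(seed, rnorm(n, 0, sqrt(1 - h2)))
  if (config$trait_type == "case_control") {
    y <- as.numeric(y > qnorm(1 - config$prevalence))
  }
  y
}

#' Per-variant association summary statistics
#'
#' Simple linear regression of the phenotype on each dosage column (the
#' default also for 0/1 outcomes, where the linear model on the observed scale
#' is a fast, well-calibrated score test; a logistic mode reports per-variant
#' log-odds instead). Optional covariates are residualised out of the
#' phenotype first. p-values are two-sided normal, so stored p and beta/se are
#' exactly consistent. Monomorphic variants are emitted with `info = 0` and a
#' unit-less placeholder effect so that default QC removes them.
#'
#' @param panel An [ld_panel()].
#' @param y Phenotype vector.
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param covariates Optional numeric matrix of covariates.
#' @param method `"linear"` (vectorised OLS) or `"logistic"` (per-variant glm;
#'   slower, binary traits only).
#' @param trait_id Label stored on the result.
#' @return A `gwas_sumstats` object with `info = 1` for polymorphic variants.
#' @export
compute_sumstats <- function(panel, y, trait_type = c("quantitative", "case_control"),
                             covariates = NULL, method = c("linear", "logistic"),
                             trait_id = "sim_trait") {
  trait_type <- match.arg(trait_type)
  method <- match.arg(method)
  G <- panel$dosages
  n <- nrow(G)
  if (!is.null(covariates)) {
    y <- stats::resid(lm(y ~ covariates))
  }
  eaf <- colMeans(G) / 2
  if (method == "logistic") {
    fits <- apply(G, 2, function(g) {
      if (stats::sd(g) == 0) return(c(0, NA))
      f <- stats::glm(y ~ g, family = stats::binomial())
      summary(f)$coefficients["g", 1:2]
    })
    beta <- fits[1, ]
    se <- fits[2, ]
  } else {
    yc <- y - mean(y)
    Sxy <- as.numeric(crossprod(G, yc))
    Sxx <- colSums(G^2) - n * (2 * eaf)^2
    Syy <- sum(yc^2)
    beta <- Sxy / Sxx
    sigma2 <- pmax((Syy - beta * Sxy) / (n - 2), 0)
    se <- sqrt(sigma2 / Sxx)
  }
  mono <- !is.finite(beta) | !is.finite(se) | se <= 0
  beta[mono] <- 0
  se[mono] <- 1
  z <- abs(beta / se)
  p <- pmax(2 * pnorm(-z), .Machine$double.xmin)
  info <- ifelse(mono, 0, 1)
  df <- tibble(chrom = panel$variants$chrom, pos = panel$variants$pos,
               ref = panel$variants$ref, alt = panel$variants$alt,
               eaf = eaf, beta = beta, se = se, p = p, n = n, info = info)
  as_sumstats(df, trait_id = trait_id, trait_type = trait_type)
}

#' Paired two-trait studies on one genotype law
#'
#' Draws two non-overlapping sample sets from the same genotype law (shared
#' MAF spectrum and LD structure, independent individuals) and simulates two
#' traits whose causal architecture is `shared` (one causal variant for both),
#' `distinct` (two causal variants whose model-implied r-squared is below
#' `r2_cap`), or `independent` (second trait null).
#'
#' @param config A [sim_config()]; its `causal` slot, if any, supplies the
#'   first trait's causal variant, otherwise one is drawn uniformly.
#' @param mode `"shared"`, `"distinct"` or `"independent"`.
#' @param ve Variance explained by each causal variant (default 0.01).
#' @param r2_cap Maximum model-implied LD r-squared between distinct causal
#'   variants (default 0.01).
#' @return List with `ss1`, `ss2` (`gwas_sumstats`), `panel1`, `panel2`
#'   (`ld_panel`), and `truth` (a one-row tibble with mode and causal indices).
#' @export
make_paired_studies <- function(config, mode = c("shared", "distinct", "independent"),
                                ve = 0.01, r2_cap = 0.01) {
  mode <- match.arg(mode)
  m <- config$n_variants
  rho_of <- rep(config$blocks$rho, config$blocks$length)
  block_of <- rep(seq_len(nrow(config$blocks)), config$blocks$length)

  picks <- withr_seed(config$seed + 10L, {
    c1 <- if (!is.null(config$causal)) config$causal$index[1] else sample.int(m, 1)
    c2 <- NA_integer_
    if (mode == "shared") c2 <- c1
    if (mode == "distinct") {
      # latent correlation between i and j is prod of rho over the path when in
      # one block, 0 across blocks; genotype r is bounded above by it
      lat_r <- function(i, j) {
        if (block_of[i] != block_of[j]) return(0)
        rho_of[i]^abs(i - j)
      }
      ok <- which(vapply(seq_len(m), function(j) {
        j != c1 && lat_r(c1, j)^2 < r2_cap
      }, logical(1)))
      if (length(ok) == 0) abort("no variant satisfies the distinct-causal r2 cap")
      c2 <- ok[sample.int(length(ok), 1)]
    }
    list(c1 = c1, c2 = c2)
  })

  cfg1 <- config
  cfg1$causal <- tibble(index = picks$c1, ve = ve)
  cfg2 <- config
  cfg2$causal <- switch(mode,
    shared = tibble(index = picks$c1, ve = ve),
    distinct = tibble(index = picks$c2, ve = ve),
    independent = NULL)

  panel1 <- simulate_genotypes(config, seed = config$seed + 1L)
  panel2 <- simulate_genotypes(config, seed = config$seed + 2L)
  y1 <- simulate_trait(panel1, cfg1, seed = config$seed + 3L)
  y2 <- simulate_trait(panel2, cfg2, seed = config$seed + 4L)
  ss1 <- compute_sumstats(panel1, y1, trait_type = config$trait_type, trait_id = "trait1")
  ss2 <- compute_sumstats(panel2, y2, trait_type = config$trait_type, trait_id = "trait2")
  truth <- tibble(mode = mode, causal1 = picks$c1,
                  causal2 = if (mode == "shared") picks$c1 else picks$c2)
  list(ss1 = ss1, ss2 = ss2, panel1 = panel1, panel2 = panel2, truth = truth)
}
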