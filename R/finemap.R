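#' Estimate the phenotype standard deviation from summary statistics
#'
#' For a quantitative trait, under simple regression the variant-level
#' quantities satisfy \eqn{2 n_j f_j (1 - f_j) \approx \sigma^2 / Var(\beta_j)},
#' with \eqn{f_j} the minor-allele frequency. Regressing
#' \eqn{y_j = 2 n_j f_j (1 - f_j)} on \eqn{x_j = 1 / Var(\beta_j)} through the
#' origin estimates \eqn{\sigma^2} as the slope; its square root is the
#' phenotype SD (often called sdY).
#'
#' @param ss A `gwas_sumstats` object (or plain data frame with `eaf`, `se`,
#'   `n`) for a quantitative trait; needs at least 2 variants with distinct
#'   `1/Var(beta)`.
#' @return The estimated phenotype standard deviation.
#' @export
estimate_sdY <- function(ss) {
  df <- as_tibble(ss)
  if (nrow(df) < 2) abort("estimate_sdY needs at least 2 variants")
  f <- pmin(df$eaf, 1 - df$eaf)
  x <- 1 / df$se^2
  if (length(unique(x)) < 2) abort("estimate_sdY needs distinct 1/Var(beta) values")
  yv <- 2 * df$n * f * (1 - f)
  slope <- coef(lm(yv ~ x - 1))[[1]]
  if (!is.finite(slope) || slope <= 0) {
    abort("non-positive sdY regression slope: inconsistent inputs",
          class = "postgwas_sdy_error")
  }
  sqrt(slope)
}

#' Prior effect-size variance for the Wakefield ABF
#'
#' \eqn{\omega = 0.2^2} on the log-odds scale for case-control traits and
#' \eqn{(0.15\sigma)^2} for quantitative traits, where \eqn{\sigma} is the
#' phenotype SD (see [estimate_sdY()]).
#'
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param sigma Phenotype SD; required for quantitative traits.
#' @return The prior variance \eqn{\omega}.
#' @export
effect_prior_variance <- function(trait_type = c("quantitative", "case_control"),
                                  sigma = NULL) {
  trait_type <- match.arg(trait_type)
  if (trait_type == "case_control") return(0.2^2)
  if (is.null(sigma)) abort("quantitative traits need `sigma` to set the prior variance")
  (0.15 * sigma)^2
}

#' Priors and cutoffs for ABF fine-mapping
#'
#' @param omega Prior effect-size variance; if `NULL`, derived from
#'   `trait_type` and `sigma` via [effect_prior_variance()].
#' @param gamma Prior probability that the region harbours no association
#'   (default 0.05, matching a 5% false-discovery expectation for loci
#'   discovered at genome-wide significance).
#' @param cutoff Credible-set mass cutoff `c` (default 0.95).
#' @param trait_type,sigma Passed to [effect_prior_variance()] when `omega`
#'   is `NULL`.
#' @return An `abf_priors` list.
#' @export
abf_priors <- function(omega = NULL, gamma = 0.05, cutoff = 0.95,
                       trait_type = c("quantitative", "case_control"),
                       sigma = NULL) {
  trait_type <- match.arg(trait_type)
  if (is.null(omega)) omega <- effect_prior_variance(trait_type, sigma)
  stopifnot(omega > 0, gamma >= 0, gamma < 1, cutoff > 0, cutoff < 1)
  structure(list(omega = omega, gamma = gamma, cutoff = cutoff,
                 trait_type = trait_type),
            class = "abf_priors")
}

#' Wakefield log approximate Bayes factor
#'
#' The natural log of the approximate Bayes factor favouring association at a
#' single variant with estimated effect `beta`, sampling variance `V`, and a
#' normal effect prior with variance `omega`:
#' \deqn{\Lambda = \tfrac12 \ln\frac{V}{V+\omega} +
#'       \frac{\omega \beta^2}{2 V (V+\omega)}.}
#' Vectorised over all arguments.
#'
#' @param beta Estimated allelic effect (log odds ratio for case-control).
#' @param V Variance of the estimate (`se^2`), positive.
#' @param omega Prior effect-size variance, positive.
#' @return The log-ABF \eqn{\Lambda} (log scale; > 0 favours association).
#' @export
log_abf <- function(beta, V, omega) {
  stopifnot(all(V > 0), all(omega > 0))
  0.5 * log(V / (V + omega)) + omega * beta^2 / (2 * V * (V + omega))
}

#' Per-variant posterior probabilities with an explicit null weight
#'
#' Given log-ABFs \eqn{\Lambda_j} for the `l` variants of a region, the
#' posterior that variant j drives the association is
#' \eqn{\pi_j \propto \frac{1-\gamma}{l} e^{\Lambda_j}}, with the no-association
#' configuration receiving weight \eqn{\gamma} (its Bayes factor is 1).
#' Computed with log-sum-exp for numerical stability.
#'
#' @param lambdas Numeric vector of log-ABFs.
#' @param priors An [abf_priors()] object (only `gamma` is used).
#' @return List with `pi` (per-variant posteriors) and `pi0` (posterior mass
#'   on no association); `pi0 + sum(pi) == 1`.
#' @export
posterior_probs <- function(lambdas, priors = abf_priors(omega = 1)) {
  l <- length(lambdas)
  stopifnot(l >= 1)
  gamma <- priors$gamma
  logw <- c(log(gamma), log1p(-gamma) - log(l) + lambdas)
  logz <- lse(logw)
  w <- exp(logw - logz)
  list(pi = w[-1], pi0 = w[1])
}

#' Construct a credible set from per-variant posteriors
#'
#' Variants are sorted by decreasing log-ABF (ties: decreasing \eqn{|\beta|/
#' \sqrt V}, then position) and accumulated on the renormalised scale
#' \eqn{\pi_j / (1 - \pi_0)} until the running mass reaches the cutoff `c`.
#' Renormalisation makes membership independent of `gamma` and guarantees a
#' c-level set exists even when \eqn{\pi_0 > 1 - c}; \eqn{\pi_0} is reported
#' alongside so callers can gate on it.
#'
#' @param variants Data frame of the region's variants, aligned with
#'   `lambdas`; needs `beta` and `se` for tie-breaking and `pos` if present.
#' @param lambdas Log-ABFs from [log_abf()].
#' @param priors An [abf_priors()] object.
#' @return A `credible_set`: a tibble sorted by posterior with columns
#'   `log_abf`, `pi`, `pi_renorm`, `cumulative`, `in_set`, carrying `pi0`,
#'   `omega`, `gamma`, `cutoff` and `n_members` attributes.
#' @export
credible_set <- function(variants, lambdas, priors) {
  df <- as_tibble(variants)
  stopifnot(nrow(df) == length(lambdas))
  pp <- posterior_probs(lambdas, priors)
  if (1 - pp$pi0 <= 0) {
    abort("degenerate posterior: all mass on the null configuration",
          class = "postgwas_degenerate_posterior")
  }
  zmag <- abs(df$beta) / df$se
  pos <- if ("pos" %in% names(df)) df$pos else seq_along(lambdas)
  o <- order(-lambdas, -zmag, pos)
  df <- df[o, , drop = FALSE]
  df$log_abf <- lambdas[o]
  df$pi <- pp$pi[o]
  # renormalised over variants: gamma cancels, so membership is gamma-free
  ren <- exp(df$log_abf - lse(df$log_abf))
  df$pi_renorm <- ren
  df$cumulative <- cumsum(ren)
  # accumulated float error on a long cumsum must not push the boundary
  # member out (e.g. 95 exact 0.01 masses at c = 0.95)
  k <- which(df$cumulative >= priors$cutoff - 1e-9)[1]
  if (is.na(k)) k <- nrow(df)  # guard against terminal rounding below c
  df$in_set <- seq_len(nrow(df)) <= k
  structure(df, class = c("credible_set", class(tibble())),
            pi0 = pp$pi0, omega = priors$omega, gamma = priors$gamma,
            cutoff = priors$cutoff, n_members = k)
}

#' Fine-map a region of summary statistics
#'
#' Convenience wrapper: computes `V = se^2`, derives `omega` from the trait
#' type (estimating the phenotype SD from the region's summary statistics for
#' quantitative traits) unless supplied, and returns the credible set.
#'
#' @param ss A `gwas_sumstats` object restricted to the fine-mapping region
#'   (typically the post-QC, MHC-masked variants within 500 kb of the index).
#' @param priors Optional [abf_priors()]; defaults to trait-appropriate
#'   `omega`, `gamma = 0.05`, `cutoff = 0.95`.
#' @return A `credible_set`.
#' @export
finemap_region <- function(ss, priors = NULL) {
  df <- as_tibble(ss)
  if (is.null(priors)) {
    tt <- trait_type(ss)
    sigma <- if (tt == "quantitative") estimate_sdY(df) else NULL
    priors <- abf_priors(trait_type = tt, sigma = sigma)
  }
  lambdas <- log_abf(df$beta, df$se^2, priors$omega)
  credible_set(df, lambdas, priors)
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("<credible_set> %d/%d variants reach %.0f%% mass (pi0 = %.3g, omega = %.4g, gamma = %.2g)\n",
              attr(x, "n_members"), nrow(x), 100 * attr(x, "cutoff"),
              attr(x, "pi0"), attr(x, "omega"), attr(x, "gamma")))
  NextMethod()
}

#' @export
tidy.credible_set <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.credible_set <- function(x, ...) {
  tibble(n_variants = nrow(x), n_members = attr(x, "n_members"),
         pi0 = attr(x, "pi0"), omega = attr(x, "omega"),
         gamma = attr(x, "gamma"), cutoff = attr(x, "cutoff"),
         top_pi = x$pi_renorm[1])
}

#' Write a fine-mapping result as TSV plus a JSON provenance sidecar
#'
#' @param x A `credible_set`.
#' @param path Output TSV path; the sidecar goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_credible_set <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  jsonlite::write_json(
    list(omega = attr(x, "omega"), gamma = attr(x, "gamma"),
         cutoff = attr(x, "cutoff"), pi0 = attr(x, "pi0"),
         n_members = attr(x, "n_members"),
         sort = "decreasing log-ABF", mass = "renormalised over variants"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
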