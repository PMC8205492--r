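#' Credible-set coverage calibration
#'
#' Monte-Carlo check of fine-mapping calibration under the generating prior:
#' in each replicate one of `l` LD-free variants is causal (uniformly), its
#' effect is drawn from the analysis prior `N(0, omega)`, and per-variant
#' effect estimates are drawn at a sampling variance chosen so the causal
#' variant's median association chi-square equals `target_chi2_median`.
#' Coverage is the fraction of replicates whose `cutoff`-level credible set
#' contains the causal variant. Because the stopping rule includes the
#' boundary variant, expected coverage equals the expected stopping mass,
#' which exceeds `cutoff` when posteriors concentrate on few variants.
#'
#' @param n_reps Number of replicates.
#' @param l Variants per region.
#' @param target_chi2_median Median chi-square of the causal variant.
#' @param omega,gamma,cutoff Fine-mapping priors (defaults: standardised
#'   quantitative trait).
#' @param seed Integer seed.
#' @return List with `coverage`, `mean_set_size`, `mean_stop_mass`, `n_reps`.
#' @export
calibrate_credible_sets <- function(n_reps = 2000, l = 50,
                                    target_chi2_median = 30, omega = 0.0225,
                                    gamma = 0.05, cutoff = 0.95, seed = 1) {
  V <- omega * CHISQ1_MEDIAN / (target_chi2_median - CHISQ1_MEDIAN)
  pr <- abf_priors(omega = omega, gamma = gamma, cutoff = cutoff)
  vars <- tibble(pos = seq_len(l), se = sqrt(V))
  withr_seed(seed, {
    hits <- logical(n_reps)
    sizes <- integer(n_reps)
    mass <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      causal <- sample.int(l, 1)
      b <- rnorm(1, 0, sqrt(omega))
      bhat <- rnorm(l, 0, sqrt(V))
      bhat[causal] <- bhat[causal] + b
      vars$beta <- bhat
      cs <- credible_set(vars, log_abf(bhat, V, omega), pr)
      k <- attr(cs, "n_members")
      hits[r] <- causal %in% cs$pos[cs$in_set]
      sizes[r] <- k
      mass[r] <- cs$cumulative[k]
    }
  })
  list(coverage = mean(hits), mean_set_size = mean(sizes),
       mean_stop_mass = mean(mass), n_reps = n_reps)
}

#' Signal-recovery calibration for approximate conditional analysis
#'
#' Simulates loci with one or two planted causal variants (two causals sit in
#' separate LD blocks, so their model-implied r-squared is ~0; each explains
#' `ve` of the trait variance), runs [stepwise_conditional()] against the
#' in-sample LD panel, and scores a replicate as recovered when every causal
#' variant is tagged by a distinct reported signal at panel r-squared >=
#' `tag_r2` and, for the single-causal design, exactly one signal is reported.
#'
#' @param n_reps Replicates.
#' @param n_causal 1 or 2.
#' @param n_samples GWAS sample size per replicate.
#' @param ve Variance explained per causal variant.
#' @param n_variants Variants per locus.
#' @param rho Latent AR(1) neighbour correlation within a block.
#' @param p_joint_max Conditional-independence threshold.
#' @param tag_r2 LD threshold for counting a signal as tagging a causal.
#' @param seed Integer seed.
#' @return List with `recovery`, `mean_signals`, `n_reps`.
#' @export
calibrate_signal_recovery <- function(n_reps = 200, n_causal = 1,
                                      n_samples = 5000, ve = 0.01,
                                      n_variants = 100, rho = 0.9,
                                      p_joint_max = 1e-8, tag_r2 = 0.8,
                                      seed = 1) {
  stopifnot(n_causal %in% 1:2)
  blocks <- if (n_causal == 1) {
    data.frame(length = n_variants, rho = rho)
  } else {
    data.frame(length = rep(n_variants / 2, 2), rho = rho)
  }
  causal_idx <- if (n_causal == 1) round(n_variants / 2) else
    c(round(n_variants / 4), round(3 * n_variants / 4))
  ok <- logical(n_reps)
  nsig <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(n_samples, n_variants, blocks = blocks,
                      causal = data.frame(index = causal_idx, ve = ve),
                      seed = seed + 7L * r)
    panel <- simulate_genotypes(cfg)
    y <- simulate_trait(panel, cfg)
    ss <- compute_sumstats(panel, y)
    sig <- stepwise_conditional(ss, panel, list(members = seq_len(n_variants)),
                                p_joint_max = p_joint_max)
    nsig[r] <- nrow(sig)
    if (nrow(sig) > 0) {
      lead_cols <- match(sig$pos, panel$variants$pos)
      R <- suppressWarnings(
        cor(panel$dosages[, causal_idx, drop = FALSE],
            panel$dosages[, lead_cols, drop = FALSE]))
      each_tagged <- all(vapply(seq_len(n_causal), function(k) {
        any(R[k, ]^2 >= tag_r2)
      }, logical(1)))
      distinct_tags <- n_causal == 1 ||
        length(unique(apply(R^2, 1, which.max))) == n_causal
      ok[r] <- each_tagged && distinct_tags &&
        (n_causal > 1 || nrow(sig) == 1)
    }
  }
  list(recovery = mean(ok), mean_signals = mean(nsig), n_reps = n_reps)
}

#' Colocalisation classification calibration
#'
#' Simulates paired two-trait studies ([make_paired_studies()]) and scores the
#' posterior concentration on the true configuration: PP4 for a shared causal
#' variant, PP3 for distinct causal variants, PP0+PP1 for an independent
#' (null) second trait; also reports how often the strong-colocalisation rule
#' fires.
#'
#' @param n_reps Replicates.
#' @param mode `"shared"`, `"distinct"` or `"independent"`.
#' @param n_samples Samples per study.
#' @param n_variants Region size.
#' @param ve Variance explained per causal variant.
#' @param rho Latent AR(1) neighbour correlation (blocks of 50).
#' @param seed Integer seed.
#' @return List with `rate` (fraction of replicates with the true
#'   configuration's posterior > 0.9), `strong_coloc_rate`, `mean_pp`
#'   (average posterior vector), `n_reps`.
#' @export
calibrate_coloc <- function(n_reps = 200, mode = c("shared", "distinct", "independent"),
                            n_samples = 5000, n_variants = 200, ve = 0.01,
                            rho = 0.9, seed = 1) {
  mode <- match.arg(mode)
  blocks <- data.frame(length = rep(50, n_variants / 50), rho = rho)
  hit <- logical(n_reps)
  strong <- logical(n_reps)
  pps <- matrix(0, n_reps, 5)
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(n_samples, n_variants, blocks = blocks,
                      seed = seed + 11L * r)
    pair <- make_paired_studies(cfg, mode = mode, ve = ve)
    res <- coloc_posteriors(harmonise_pair(pair$ss1, pair$ss2))
    pps[r, ] <- res$pp
    hit[r] <- switch(mode,
                     shared = res$pp[["PP4"]] > 0.9,
                     distinct = res$pp[["PP3"]] > 0.9,
                     independent = res$pp[["PP0"]] + res$pp[["PP1"]] > 0.9)
    strong[r] <- res$decision == "strong_coloc"
  }
  list(rate = mean(hit), strong_coloc_rate = mean(strong),
       mean_pp = setNames(colMeans(pps), paste0("PP", 0:4)), n_reps = n_reps)
}

#' Null-GWAS calibration
#'
#' Fully null simulated scans (independent variants, so the set is its own
#' LD-pruned representative): per seed, the genomic-control lambda and the
#' number of loci at the study-wide threshold.
#'
#' @param n_seeds Number of independent scans.
#' @param n_samples,n_variants Scan dimensions.
#' @param p_threshold Locus-defining threshold (default 5e-8/11).
#' @param seed Integer seed.
#' @return Tibble with one row per scan: `lambda_gc`, `n_loci`.
#' @export
calibrate_null_gwas <- function(n_seeds = 50, n_samples = 5000,
                                n_variants = 10000,
                                p_threshold = 5e-8 / 11, seed = 1) {
  purrr::map_dfr(seq_len(n_seeds), function(s) {
    cfg <- sim_config(n_samples, n_variants, seed = seed + 13L * s)
    panel <- simulate_genotypes(cfg)
    ss <- compute_sumstats(panel, simulate_trait(panel, cfg))
    tibble(lambda_gc = genomic_inflation(ss),
           n_loci = nrow(find_loci(ss, p_threshold)))
  })
}

#' Phenotype-SD recovery calibration
#'
#' End-to-end check of [estimate_sdY()]: a simulated GWAS of a trait with unit
#' phenotypic SD, summary statistics, and the recovered SD.
#'
#' @param n_samples,n_variants Scan dimensions.
#' @param seed Integer seed.
#' @return List with `sigma_hat` and `rel_err` (against the generating SD 1).
#' @export
calibrate_sdy <- function(n_samples = 10000, n_variants = 500, seed = 1) {
  cfg <- sim_config(n_samples, n_variants, seed = seed)
  panel <- simulate_genotypes(cfg)
  ss <- compute_sumstats(panel, simulate_trait(panel, cfg))
  sigma_hat <- estimate_sdY(ss)
  list(sigma_hat = sigma_hat, rel_err = abs(sigma_hat - 1))
}
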