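#' Harmonise two summary-statistics tables over a region
#'
#' Intersects on (chrom, pos), aligns the second trait's effect allele to the
#' first's (ref/alt swaps flip the sign of beta and complement eaf), drops
#' allele-mismatched pairs, and drops strand-ambiguous variants (A/T or C/G
#' pairs) whose effect-allele frequency is in \[0.4, 0.6\], where strand
#' cannot be resolved from frequency.
#'
#' @param ss1,ss2 `gwas_sumstats` objects for the two traits.
#' @param region Optional list/vector with `chrom`, `start`, `end` restricting
#'   the comparison (1-based, closed).
#' @return A `coloc_pairs` tibble with suffixed columns (`beta1`, `se1`, `n1`,
#'   `eaf1`, `beta2`, ...); dropped-variant counts are in the `log` attribute.
#' @export
harmonise_pair <- function(ss1, ss2, region = NULL) {
  d1 <- as_tibble(ss1)
  d2 <- as_tibble(ss2)
  if (!is.null(region)) {
    region <- as.list(region)
    clip <- function(d) d[norm_chrom(d$chrom) == norm_chrom(region$chrom) &
                            d$pos >= region$start & d$pos <= region$end, ]
    d1 <- clip(d1)
    d2 <- clip(d2)
  }
  d1$.key <- paste(norm_chrom(d1$chrom), d1$pos)
  d2$.key <- paste(norm_chrom(d2$chrom), d2$pos)
  j <- dplyr::inner_join(d1, d2, by = ".key", suffix = c("1", "2"))
  if (nrow(j) == 0) abort("no shared variants between the two traits in this region",
                          class = "postgwas_empty_intersection")
  same <- j$ref1 == j$ref2 & j$alt1 == j$alt2
  swap <- j$ref1 == j$alt2 & j$alt1 == j$ref2
  n_mismatch <- sum(!same & !swap)
  j <- j[same | swap, , drop = FALSE]
  swap <- j$ref1 == j$alt2 & j$alt1 == j$ref2 & !(j$ref1 == j$ref2 & j$alt1 == j$alt2)
  j$beta2[swap] <- -j$beta2[swap]
  j$eaf2[swap] <- 1 - j$eaf2[swap]

  ambiguous_pair <- function(a, b) {
    (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "C" & b == "G") | (a == "G" & b == "C")
  }
  amb <- ambiguous_pair(toupper(j$ref1), toupper(j$alt1)) &
    j$eaf1 >= 0.4 & j$eaf1 <= 0.6
  n_amb <- sum(amb)
  j <- j[!amb, , drop = FALSE]

  out <- j[c("chrom1", "pos1", "ref1", "alt1", "eaf1", "beta1", "se1", "p1", "n1",
             "eaf2", "beta2", "se2", "p2", "n2")]
  names(out)[1:4] <- c("chrom", "pos", "ref", "alt")
  structure(out, class = c("coloc_pairs", class(tibble())),
            n_flipped = sum(swap),
            log = tibble(event = c("allele_mismatch", "strand_ambiguous_dropped"),
                         removed = c(n_mismatch, n_amb)))
}

# log(exp(a) - exp(b)) for a >= b
logdiff <- function(a, b) {
  if (b == -Inf) return(a)
  a + log1p(-exp(b - a))
}

#' Colocalisation priors
#'
#' Per-variant prior probabilities that a variant is associated with trait 1
#' only (`p1`), trait 2 only (`p2`), or both (`p12`). Defaults are the
#' conventional 1e-4, 1e-4, 1e-5.
#'
#' @param p1,p2,p12 Priors; must satisfy `0 < p12 <= p1, p2 < 1`.
#' @return A `coloc_priors` list.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(p12 > 0, p12 <= p1, p12 <= p2, p1 < 1, p2 < 1)
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' ABF colocalisation posteriors for two traits
#'
#' Enumerates the five causal configurations of a region with `l` variants
#' under the single-causal-variant assumption per trait: no association (H0),
#' trait 1 only (H1), trait 2 only (H2), two distinct causal variants (H3),
#' one shared causal variant (H4). Per-variant evidence enters through
#' Wakefield log-ABFs for each trait; configuration sums are computed in log
#' space (H3 excludes same-variant pairs, by direct enumeration of the `l^2`
#' ordered pairs when `l <= 200` and by log-space subtraction of the diagonal
#' otherwise).
#'
#' @param pairs A `coloc_pairs` tibble from [harmonise_pair()].
#' @param priors A [coloc_priors()] object.
#' @param omega1,omega2 Prior effect-size variances for the two traits; if
#'   `NULL`, each is derived from the quantitative-trait convention with the
#'   phenotype SD estimated from that trait's columns (pass `0.04` explicitly
#'   for case-control traits).
#' @return A `coloc_result`: list with `pp` (named PP0..PP4 summing to 1),
#'   `n_variants`, `decision` (see [coloc_decision()]), and the priors used.
#' @export
coloc_posteriors <- function(pairs, priors = coloc_priors(),
                             omega1 = NULL, omega2 = NULL) {
  l <- nrow(pairs)
  stopifnot(l >= 1)
  if (is.null(omega1)) {
    omega1 <- effect_prior_variance("quantitative",
      sigma = estimate_sdY(tibble(eaf = pairs$eaf1, se = pairs$se1, n = pairs$n1)))
  }
  if (is.null(omega2)) {
    omega2 <- effect_prior_variance("quantitative",
      sigma = estimate_sdY(tibble(eaf = pairs$eaf2, se = pairs$se2, n = pairs$n2)))
  }
  l1 <- log_abf(pairs$beta1, pairs$se1^2, omega1)
  l2 <- log_abf(pairs$beta2, pairs$se2^2, omega2)
  s1 <- lse(l1)
  s2 <- lse(l2)
  s4 <- lse(l1 + l2)
  s3 <- if (l == 1) {
    -Inf
  } else if (l <= 200) {
    grid <- outer(l1, l2, "+")
    diag(grid) <- -Inf
    lse(as.vector(grid))
  } else {
    logdiff(s1 + s2, s4)
  }
  logh <- c(PP0 = 0,
            PP1 = log(priors$p1) + s1,
            PP2 = log(priors$p2) + s2,
            PP3 = log(priors$p1) + log(priors$p2) + s3,
            PP4 = log(priors$p12) + s4)
  pp <- exp(logh - lse(logh))
  res <- structure(list(pp = pp, n_variants = l, priors = priors,
                        omega = c(omega1 = omega1, omega2 = omega2),
                        decision = NA_character_),
                   class = "coloc_result")
  res$decision <- coloc_decision(res)
  res
}

#' Strong-colocalisation decision rule
#'
#' `strong_coloc` when `PP3 + PP4 >= 0.99` and `PP4 / PP3 >= 5` (a zero PP3
#' yields an infinite ratio, which satisfies the rule); the symmetric
#' `distinct` label (same sum with `PP3 / PP4 >= 5`) is a package addition for
#' reporting convenience; anything else is `inconclusive`.
#'
#' @param result A `coloc_result` (or a numeric vector of five posteriors
#'   PP0..PP4).
#' @return One of `"strong_coloc"`, `"distinct"`, `"inconclusive"`.
#' @export
coloc_decision <- function(result) {
  pp <- if (inherits(result, "coloc_result")) result$pp else result
  pp3 <- pp[[4]]
  pp4 <- pp[[5]]
  if (pp3 + pp4 >= 0.99) {
    r <- pp4 / pp3  # Inf when pp3 == 0 (and pp4 > 0), NaN only if both 0
    if (is.finite(r) || (is.infinite(r) && pp4 > 0)) {
      if (r >= 5) return("strong_coloc")
      if (1 / r >= 5) return("distinct")
    }
  }
  "inconclusive"
}

#' Colocalise two traits over a signal's region
#'
#' Convenience wrapper: harmonises the two summary-statistics tables over the
#' +/- `flank_bp` window around `index_pos`, then computes posteriors and the
#' decision.
#'
#' @param ss1,ss2 `gwas_sumstats` objects.
#' @param chrom,index_pos Signal location; the region is
#'   `index_pos +/- flank_bp`.
#' @param flank_bp Window half-width (default 500,000 bp).
#' @param ... Passed to [coloc_posteriors()].
#' @return A `coloc_result`.
#' @export
coloc_region <- function(ss1, ss2, chrom, index_pos, flank_bp = 500000L, ...) {
  region <- list(chrom = chrom, start = max(1, index_pos - flank_bp),
                 end = index_pos + flank_bp)
  pairs <- harmonise_pair(ss1, ss2, region)
  coloc_posteriors(pairs, ...)
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> l = %d variants; decision: %s\n", x$n_variants, x$decision))
  print(round(x$pp, 4))
  invisible(x)
}

#' @export
tidy.coloc_result <- function(x, ...) {
  tibble(hypothesis = names(x$pp), posterior = unname(x$pp))
}

#' @export
glance.coloc_result <- function(x, ...) {
  tibble(PP0 = x$pp[["PP0"]], PP1 = x$pp[["PP1"]], PP2 = x$pp[["PP2"]],
         PP3 = x$pp[["PP3"]], PP4 = x$pp[["PP4"]],
         n_variants = x$n_variants, decision = x$decision)
}
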