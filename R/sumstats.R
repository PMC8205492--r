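#' Column dialect for summary-statistics files
#'
#' GWAS deposits name their columns inconsistently; a dialect maps the on-disk
#' header names onto the canonical names used throughout this package. The
#' `info` column is optional: when absent, imputation quality defaults to 1
#' (genotyped / simulated variants).
#'
#' @param chrom,pos,ref,alt,eaf,beta,se,p,n,info On-disk column names.
#' @return A named character vector usable as the `dialect` argument of
#'   [read_sumstats()].
#' @export
#' @examples
#' sumstats_dialect(chrom = "CHR", pos = "BP", p = "P_BOLT_LMM")
sumstats_dialect <- function(chrom = "chrom", pos = "pos", ref = "ref",
                             alt = "alt", eaf = "eaf", beta = "beta",
                             se = "se", p = "p", n = "n", info = "info") {
  c(chrom = chrom, pos = pos, ref = ref, alt = alt, eaf = eaf,
    beta = beta, se = se, p = p, n = n, info = info)
}

ss_required_cols <- c("chrom", "pos", "ref", "alt", "eaf", "beta", "se", "p", "n")

new_sumstats <- function(records, trait_id, trait_type, build, qc_log) {
  stopifnot(is.data.frame(records))
  out <- as_tibble(records)
  attr(out, "trait_id") <- trait_id
  attr(out, "trait_type") <- trait_type
  attr(out, "build") <- build
  attr(out, "qc_log") <- qc_log
  class(out) <- c("gwas_sumstats", class(tibble()))
  out
}

log_filter <- function(ss, filter, removed) {
  lg <- dplyr::bind_rows(attr(ss, "qc_log"),
                         tibble(filter = filter, removed = as.integer(removed)))
  attr(ss, "qc_log") <- lg
  ss
}

#' QC provenance of a summary-statistics table
#'
#' @param ss A `gwas_sumstats` object.
#' @return A tibble with one row per filter applied and the number of variants
#'   it removed. The counts sum to the difference between input and output
#'   sizes across the object's history.
#' @export
qc_log <- function(ss) {
  attr(ss, "qc_log") %||% tibble(filter = character(), removed = integer())
}

#' @export
trait_type <- function(ss) attr(ss, "trait_type") %||% "quantitative"

#' @export
trait_id <- function(ss) attr(ss, "trait_id") %||% "trait"

# sort by chromosome (numerically where possible) then position
sort_records <- function(df) {
  cn <- norm_chrom(df$chrom)
  num <- suppressWarnings(as.numeric(cn))
  df[order(is.na(num), num, cn, df$pos), , drop = FALSE]
}

# relative z-score agreement between the stored p and beta/se under a
# two-sided normal test; tolerance floored at 1 so p ~ 1 records pass
z_consistent <- function(beta, se, p, tol = 1e-6) {
  z <- abs(beta / se)
  zp <- qnorm(pmin(p, 1) / 2, lower.tail = FALSE)
  abs(z - zp) <= tol * pmax(1, zp)
}

#' Assemble a summary-statistics object from a data frame
#'
#' Validates per-variant invariants (`se > 0`, `eaf` in \[0,1\], `p` in (0,1\],
#' `pos >= 1`, and p consistent with `beta/se` under a two-sided normal test to
#' 1e-6 relative tolerance on the z-score), drops failing rows with a QC-log
#' entry, de-duplicates on (chrom, pos, ref, alt) and sorts by position.
#'
#' @param df Data frame with columns chrom, pos, ref, alt, eaf, beta, se, p, n
#'   and optionally info (defaulted to 1).
#' @param trait_id Label for the trait.
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param build Genome-build tag (default `"GRCh37"`).
#' @return A `gwas_sumstats` tibble carrying `trait_id`, `trait_type`, `build`
#'   and a `qc_log` attribute (see [qc_log()]).
#' @export
as_sumstats <- function(df, trait_id = "trait", trait_type = c("quantitative", "case_control"),
                        build = "GRCh37") {
  trait_type <- match.arg(trait_type)
  missing <- setdiff(ss_required_cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s): ", paste(missing, collapse = ", ")),
          class = "postgwas_format_error")
  }
  df <- as_tibble(df)
  if (!"info" %in% names(df)) df$info <- 1
  df <- df[c(ss_required_cols, "info")]
  df$chrom <- as.character(df$chrom)

  ok <- !is.na(df$pos) & df$pos >= 1 &
    !is.na(df$se) & df$se > 0 &
    !is.na(df$eaf) & df$eaf >= 0 & df$eaf <= 1 &
    !is.na(df$p) & df$p > 0 & df$p <= 1 &
    !is.na(df$beta) & !is.na(df$n)
  ok[ok] <- z_consistent(df$beta[ok], df$se[ok], df$p[ok])
  n_bad <- sum(!ok)
  df <- df[ok, , drop = FALSE]

  dup <- duplicated(df[c("chrom", "pos", "ref", "alt")])
  n_dup <- sum(dup)
  df <- sort_records(df[!dup, , drop = FALSE])

  qc <- tibble(filter = character(), removed = integer())
  ss <- new_sumstats(df, trait_id, trait_type, build, qc)
  if (n_bad > 0) ss <- log_filter(ss, "invalid_record", n_bad)
  if (n_dup > 0) ss <- log_filter(ss, "duplicate_record", n_dup)
  ss
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Reads a (possibly gzip-compressed) TSV with a header, renames columns per
#' `dialect`, and validates records as in [as_sumstats()]. Rows that fail to
#' parse as numbers are collected and skipped with a QC-log entry.
#'
#' @param path File path (plain or `.gz`).
#' @param dialect Column mapping from [sumstats_dialect()].
#' @inheritParams as_sumstats
#' @return A `gwas_sumstats` object.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(), trait_id = "trait",
                          trait_type = c("quantitative", "case_control"),
                          build = "GRCh37") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- dialect[ss_required_cols]
  missing <- need[!need %in% names(raw)]
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s): ", paste(missing, collapse = ", ")),
          class = "postgwas_format_error")
  }
  have_info <- !is.na(dialect["info"]) && dialect[["info"]] %in% names(raw)
  take <- if (have_info) dialect[c(ss_required_cols, "info")] else need
  df <- raw[unname(take)]
  names(df) <- names(take)

  num_cols <- setdiff(names(df), c("chrom", "ref", "alt"))
  parsed <- df
  for (cc in num_cols) parsed[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  bad_parse <- rowSums(is.na(parsed[num_cols]) & !is.na(df[num_cols])) > 0
  parsed <- parsed[!bad_parse, , drop = FALSE]

  ss <- as_sumstats(parsed, trait_id = trait_id, trait_type = trait_type, build = build)
  if (sum(bad_parse) > 0) ss <- log_filter(ss, "unparseable_row", sum(bad_parse))
  ss
}

#' Write summary statistics to a tab-delimited file
#'
#' Doubles are serialised with shortest round-trippable representations, so a
#' write/read cycle reproduces every field bit-exact.
#'
#' @param ss A `gwas_sumstats` object.
#' @param path Output path; a `.gz` suffix compresses transparently.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  readr::write_tsv(as_tibble(ss)[c(ss_required_cols, "info")], path, progress = FALSE)
  invisible(path)
}

#' Minor-allele-frequency and imputation-quality filter
#'
#' Retains variants with `min(eaf, 1 - eaf) >= maf_min` and `info >= info_min`
#' (both boundaries inclusive for "pass": a variant at exactly 1% MAF or
#' info 0.9 is kept). Defaults reproduce the conventional post-imputation QC of
#' excluding MAF < 1% and imputation quality < 0.9.
#'
#' @param ss A `gwas_sumstats` object.
#' @param maf_min Minimum minor-allele frequency (default 0.01).
#' @param info_min Minimum imputation quality (default 0.9).
#' @return Filtered `gwas_sumstats` with per-filter removal counts appended to
#'   the QC log. Idempotent.
#' @export
apply_variant_qc <- function(ss, maf_min = 0.01, info_min = 0.9) {
  stopifnot(maf_min >= 0, maf_min <= 1, info_min >= 0, info_min <= 1)
  df <- as_tibble(ss)
  maf <- pmin(df$eaf, 1 - df$eaf)
  keep_maf <- maf >= maf_min
  keep_info <- df$info >= info_min
  out <- new_sumstats(df[keep_maf & keep_info, , drop = FALSE],
                      trait_id(ss), trait_type(ss), attr(ss, "build"), qc_log(ss))
  out <- log_filter(out, sprintf("maf<%g", maf_min), sum(!keep_maf))
  log_filter(out, sprintf("info<%g", info_min), sum(keep_maf & !keep_info))
}

#' The MHC region (GRCh37)
#'
#' The major histocompatibility complex interval conventionally excluded from
#' post-GWAS analyses because of its extreme LD structure:
#' chr6:28,477,797-33,448,354, 1-based, closed on both ends.
#'
#' @return A list with elements `chrom`, `start`, `end`.
#' @export
mhc_region <- function() list(chrom = "6", start = 28477797L, end = 33448354L)

#' Remove all variants inside a genomic interval
#'
#' @param ss A `gwas_sumstats` object.
#' @param region List or vector with `chrom`, `start`, `end`; 1-based, closed
#'   interval. Defaults to the MHC ([mhc_region()]).
#' @return Filtered `gwas_sumstats`, with the removal logged.
#' @export
mask_region <- function(ss, region = mhc_region()) {
  region <- as.list(region)
  stopifnot(region$start <= region$end)
  df <- as_tibble(ss)
  hit <- norm_chrom(df$chrom) == norm_chrom(region$chrom) &
    df$pos >= region$start & df$pos <= region$end
  out <- new_sumstats(df[!hit, , drop = FALSE],
                      trait_id(ss), trait_type(ss), attr(ss, "build"), qc_log(ss))
  log_filter(out, sprintf("mask_%s:%d-%d", region$chrom, region$start, region$end),
             sum(hit))
}

#' Genomic-control inflation statistic
#'
#' \eqn{\lambda_{GC}} = median of the per-variant association
#' \eqn{\chi^2 = (\beta/se)^2} divided by the median of the 1-df chi-square
#' distribution (0.4549364, used to 7 decimals rather than the rounded 0.456).
#' The caller is responsible for supplying an LD-pruned variant set, since LD
#' redundancy distorts the median.
#'
#' @param ss A `gwas_sumstats` object with at least one record.
#' @return The scalar inflation factor.
#' @export
genomic_inflation <- function(ss) {
  if (nrow(ss) == 0) abort("genomic_inflation needs at least one record")
  chi2 <- (ss$beta / ss$se)^2
  median(chi2) / CHISQ1_MEDIAN
}

#' Bonferroni threshold ledger
#'
#' Records a family-wise error rate, the number of tests, and the implied
#' per-test significance threshold `alpha / n_tests`.
#'
#' @param alpha Family-wise error rate in (0,1).
#' @param n_tests Positive integer number of tests.
#' @return An object of class `threshold_ledger`.
#' @seealso [format.threshold_ledger()] for the printing convention.
#' @export
#' @examples
#' bonferroni_threshold(5e-8, 11)
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1, n_tests == round(n_tests))
  structure(list(alpha = alpha, n_tests = as.integer(n_tests),
                 threshold = alpha / n_tests),
            class = "threshold_ledger")
}

# truncate (toward zero) to `digits` significant figures
signif_floor <- function(x, digits = 3) {
  e <- floor(log10(abs(x)))
  scale <- 10^(e - digits + 1)
  trunc(x / scale) * scale
}

#' Format a Bonferroni threshold at 3 significant figures
#'
#' The mantissa is truncated rather than rounded, so the printed threshold is
#' never looser (larger) than the exact cutoff; a variant reported significant
#' against the printed value is significant against the exact one.
#'
#' @param x A `threshold_ledger`.
#' @param digits Significant figures (default 3).
#' @param ... Unused.
#' @export
format.threshold_ledger <- function(x, digits = 3, ...) {
  v <- signif_floor(x$threshold, digits)
  format(v, scientific = TRUE, digits = digits)
}

#' @export
print.threshold_ledger <- function(x, ...) {
  cat(sprintf("Bonferroni threshold: alpha = %g over %d tests -> p < %s\n",
              x$alpha, x$n_tests, format(x)))
  invisible(x)
}

#' @export
tidy.threshold_ledger <- function(x, ...) {
  tibble(alpha = x$alpha, n_tests = x$n_tests, threshold = x$threshold)
}

#' Serialise a threshold ledger to JSON for pipeline provenance
#'
#' @param x A `threshold_ledger`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_threshold_json <- function(x, path) {
  jsonlite::write_json(list(alpha = x$alpha, n_tests = x$n_tests,
                            threshold = x$threshold),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
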