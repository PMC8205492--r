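#' Construct an LD reference panel
#'
#' A panel is a samples-by-variants matrix of allele dosages in \[0,2\]
#' (dosages, not hard calls, so imputed panels work unchanged) together with
#' the variant identities aligned to its columns.
#'
#' @param dosages Numeric matrix, `n_samples` rows by `n_variants` columns.
#' @param variants Data frame with one row per column of `dosages`; must carry
#'   `chrom` and `pos`, and usually `ref`, `alt`.
#' @param sample_ids Optional character labels for the rows.
#' @return An object of class `ld_panel`.
#' @export
ld_panel <- function(dosages, variants, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  variants <- as_tibble(variants)
  if (ncol(dosages) != nrow(variants)) {
    abort("column count of `dosages` must equal the number of variant rows")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  if (!"eaf" %in% names(variants)) {
    variants$eaf <- colMeans(dosages, na.rm = TRUE) / 2
  }
  structure(list(dosages = dosages, variants = variants,
                 sample_ids = sample_ids),
            class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("<ld_panel> %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' @export
dim.ld_panel <- function(x) dim(x$dosages)

#' Pairwise LD (Pearson correlation of dosages)
#'
#' @param panel An `ld_panel`.
#' @param i,j Column indices.
#' @return Correlation `r` in \[-1,1\]; missing dosages are handled by
#'   pairwise-complete samples.
#' @export
pairwise_r <- function(panel, i, j) {
  x <- panel$dosages[, i]
  y <- panel$dosages[, j]
  if (stats::sd(x, na.rm = TRUE) == 0 || stats::sd(y, na.rm = TRUE) == 0) {
    abort("degenerate variant: zero dosage variance",
          class = "postgwas_degenerate_variant")
  }
  cor(x, y, use = "pairwise.complete.obs")
}

#' LD correlation matrix for a set of panel columns
#'
#' @param panel An `ld_panel`.
#' @param idx Column indices (default: all).
#' @return Correlation matrix of the selected dosage columns.
#' @export
ld_matrix <- function(panel, idx = seq_len(ncol(panel$dosages))) {
  cor(panel$dosages[, idx, drop = FALSE], use = "pairwise.complete.obs")
}

#' Greedy LD pruning
#'
#' Scans variants in order (default genomic position) and drops any variant
#' whose squared correlation with an already-retained variant inside a sliding
#' window reaches `r2_max`. The boundary matches the "retain r2 < r2_max"
#' convention: a pair at exactly `r2_max` is pruned. Deterministic for a given
#' order (keep-first).
#'
#' @param panel An `ld_panel`.
#' @param r2_max Squared-correlation cutoff in (0,1\] (default 0.8).
#' @param order Integer scan order over columns; default sorts by (chrom, pos).
#' @param window_bp Window within which LD is checked (default 1 Mb).
#' @return Sorted integer vector of retained column indices.
#' @export
ld_prune <- function(panel, r2_max = 0.8, order = NULL, window_bp = 1e6) {
  stopifnot(r2_max > 0, r2_max <= 1)
  v <- panel$variants
  if (is.null(order)) {
    cn <- norm_chrom(v$chrom)
    num <- suppressWarnings(as.numeric(cn))
    order <- base::order(is.na(num), num, cn, v$pos)
  }
  kept <- integer(0)
  for (i in order) {
    near <- kept[norm_chrom(v$chrom[kept]) == norm_chrom(v$chrom[i]) &
                   abs(v$pos[kept] - v$pos[i]) <= window_bp]
    drop <- FALSE
    for (k in near) {
      if (pairwise_r(panel, i, k)^2 >= r2_max) { drop <- TRUE; break }
    }
    if (!drop) kept <- c(kept, i)
  }
  sort(kept)
}

#' Subsample a panel's individuals
#'
#' Uniform sampling without replacement, reproducible under `seed`.
#'
#' @param panel An `ld_panel`.
#' @param n Number of samples to keep.
#' @param seed Integer seed.
#' @return An `ld_panel` with `n` rows.
#' @export
subsample_panel <- function(panel, n, seed) {
  n_avail <- nrow(panel$dosages)
  if (n > n_avail) abort(sprintf("requested %d samples but only %d available", n, n_avail))
  if (n == n_avail) return(panel)
  idx <- withr_seed(seed, sample.int(n_avail, n))
  ld_panel(panel$dosages[idx, , drop = FALSE],
           panel$variants[setdiff(names(panel$variants), "eaf")],
           panel$sample_ids[idx])
}

# evaluate `expr` under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write / read a panel as plain-text files
#'
#' The dosage matrix goes to a TSV (samples in rows) and the variant table to
#' a sidecar TSV at `paste0(path, ".variants.tsv")`.
#'
#' @param panel An `ld_panel`.
#' @param path Base path for the dosage TSV.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  dos <- as_tibble(as.data.frame(panel$dosages), .name_repair = "minimal")
  names(dos) <- paste0("v", seq_len(ncol(dos)))
  readr::write_tsv(dplyr::bind_cols(tibble(sample_id = panel$sample_ids), dos),
                   path, progress = FALSE)
  readr::write_tsv(panel$variants, paste0(path, ".variants.tsv"), progress = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  dos <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  variants <- readr::read_tsv(paste0(path, ".variants.tsv"), progress = FALSE,
                              show_col_types = FALSE)
  ld_panel(as.matrix(dos[-1]), variants, dos$sample_id)
}

#' Ingest an LD panel from a VCF
#'
#' Uses the `DS` FORMAT field when present, otherwise counts alternate alleles
#' in `GT`. Requires the `vcfR` package.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @return An `ld_panel`.
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_panel_vcf requires the 'vcfR' package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  fmt <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  if (all(is.na(fmt))) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    fmt <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  variants <- tibble(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                     ref = fix$REF, alt = fix$ALT)
  ld_panel(t(fmt), variants, colnames(fmt))
}
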