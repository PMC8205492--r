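#' Define loci around index variants
#'
#' Iteratively selects the smallest-p unassigned variant with `p <
#' p_threshold` as an index and assigns every variant within `flank_bp` of it
#' to that index's locus; overlapping windows are then merged transitively,
#' and each merged locus keeps the smallest-p variant as its index. The input
#' should already be QC'd and MHC-masked. Output is deterministic and
#' invariant to record order.
#'
#' @param ss A `gwas_sumstats` object.
#' @param p_threshold Locus-defining significance threshold.
#' @param flank_bp Half-width of the locus window (default 500,000 bp; the
#'   window is clipped at position 1).
#' @return A `gwas_loci` tibble with one row per locus: `locus_id`, `chrom`,
#'   `start`, `end`, index-variant columns (`index_pos`, `index_p`, ...), the
#'   member count, and a `members` list-column of row indices into `ss`.
#' @export
find_loci <- function(ss, p_threshold = 4.5454545454545455e-09, flank_bp = 500000L) {
  df <- as_tibble(ss)
  m <- nrow(df)
  assigned <- rep(FALSE, m)
  idx_rows <- integer(0)
  repeat {
    cand <- which(!assigned & df$p < p_threshold)
    if (length(cand) == 0) break
    i <- cand[which.min(df$p[cand])]
    idx_rows <- c(idx_rows, i)
    hit <- norm_chrom(df$chrom) == norm_chrom(df$chrom[i]) &
      abs(df$pos - df$pos[i]) <= flank_bp
    assigned <- assigned | hit
  }
  if (length(idx_rows) == 0) {
    return(structure(tibble(locus_id = integer(), chrom = character(),
                            start = numeric(), end = numeric(),
                            index_row = integer(), index_pos = numeric(),
                            index_p = numeric(), n_members = integer(),
                            members = list()),
                     class = c("gwas_loci", class(tibble()))))
  }
  win <- tibble(row = idx_rows, chrom = df$chrom[idx_rows],
                start = pmax(1, df$pos[idx_rows] - flank_bp),
                end = df$pos[idx_rows] + flank_bp,
                p = df$p[idx_rows])
  win <- win[order(norm_chrom(win$chrom), win$start), ]
  # transitive interval merge per chromosome
  grp <- integer(nrow(win))
  g <- 0L
  for (k in seq_len(nrow(win))) {
    if (k == 1 || norm_chrom(win$chrom[k]) != norm_chrom(win$chrom[k - 1]) ||
        win$start[k] > max(win$end[grp == g])) {
      g <- g + 1L
    }
    grp[k] <- g
  }
  loci <- win |>
    dplyr::mutate(grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(chrom = dplyr::first(.data$chrom),
                     start = min(.data$start), end = max(.data$end),
                     index_row = .data$row[which.min(.data$p)],
                     index_p = min(.data$p), .groups = "drop") |>
    dplyr::select(-"grp")
  loci$index_pos <- df$pos[loci$index_row]
  loci$members <- purrr::pmap(loci[c("chrom", "start", "end")], function(chrom, start, end) {
    which(norm_chrom(df$chrom) == norm_chrom(chrom) & df$pos >= start & df$pos <= end)
  })
  loci$n_members <- lengths(loci$members)
  loci <- loci[order(norm_chrom(loci$chrom), loci$start), ]
  loci$locus_id <- seq_len(nrow(loci))
  out <- loci[c("locus_id", "chrom", "start", "end", "index_row", "index_pos",
                "index_p", "n_members", "members")]
  structure(out, class = c("gwas_loci", class(tibble())))
}

# align summary-stat rows to panel columns on (chrom, pos) and, when allele
# columns exist on both sides, (ref, alt)
match_panel <- function(df, panel) {
  key <- function(x) paste(norm_chrom(x$chrom), x$pos)
  match(key(df), key(panel$variants))
}

# GCTA-COJO-style joint least-squares fit reconstructed from marginal
# summary statistics plus reference LD. `d` are the per-variant X'X diagonals,
# `R` the LD correlations, `yty` the phenotype sum of squares, `n` the sample
# size. Returns NULL when the LD matrix is numerically singular.
joint_fit <- function(beta_marg, d, R, yty, n) {
  k <- length(beta_marg)
  XtX <- R * sqrt(outer(d, d))
  diag(XtX) <- d
  if (rcond(XtX) < 1e-12) return(NULL)
  Xty <- d * beta_marg
  b <- solve(XtX, Xty)
  rss <- yty - sum(b * Xty)
  sigma2 <- max(rss, yty * 1e-12) / max(n - k - 1, 1)
  se <- sqrt(sigma2 * diag(solve(XtX)))
  z <- b / se
  tibble(joint_beta = b, joint_se = se,
         p_joint = pmax(2 * pnorm(-abs(z)), .Machine$double.xmin))
}

#' Forward stepwise approximate conditional analysis
#'
#' Splits a locus into conditionally independent signals by reconstructing
#' joint multiple-regression fits from marginal summary statistics and
#' reference-panel LD, in the style of summary-data conditional/joint
#' analysis. Starting from the marginal lead, each step refits the selected
#' set plus each candidate (cross-products from panel correlations; per-
#' variant variance from `2f(1-f)n`, or the empirical panel dosage variance
#' when `var_from_panel = TRUE`; phenotypic variance from the sdY regression
#' for quantitative traits, fixed at 1 on the log-odds scale for case-control)
#' and adds the candidate with the smallest conditional p if it is below
#' `p_joint_max` and not collinear (`r2 < r2_collinear`) with the selected
#' set. After selection, a backward sweep drops any selected variant whose
#' joint p rises above `p_joint_max`, so every reported signal is
#' conditionally significant.
#'
#' @param ss A `gwas_sumstats` object covering the locus.
#' @param panel An [ld_panel()] covering the locus members.
#' @param locus One row of [find_loci()] output (or a list with a `members`
#'   integer vector of row indices into `ss`).
#' @param p_joint_max Conditional-independence threshold (default 1e-8).
#' @param r2_collinear Collinearity guard (default 0.9).
#' @param freq_diff_max Variants whose summary and panel allele frequencies
#'   differ by more than this are excluded (default 0.2).
#' @param var_from_panel Use empirical panel dosage variances for the X'X
#'   diagonal instead of the Hardy-Weinberg `2f(1-f)` form.
#' @return A `gwas_signals` tibble, one row per signal: lead-variant fields,
#'   `joint_beta`, `joint_se`, `p_joint`, and `conditional_on` (list-column of
#'   the other leads' positions). Zero rows if no variant reaches
#'   `p_joint_max`. Skipped candidates (collinear or ill-conditioned) are
#'   recorded in the `log` attribute.
#' @export
stepwise_conditional <- function(ss, panel, locus, p_joint_max = 1e-8,
                                 r2_collinear = 0.9, freq_diff_max = 0.2,
                                 var_from_panel = FALSE) {
  df <- as_tibble(ss)
  members <- if (is.list(locus) && !is.null(locus$members)) {
    if (is.list(locus$members)) locus$members[[1]] else locus$members
  } else {
    abort("`locus` must carry a `members` index vector")
  }
  sub <- df[members, , drop = FALSE]
  col <- match_panel(sub, panel)
  if (anyNA(col)) abort("LD panel is missing variants at this locus")
  log_lines <- character(0)

  pan_eaf <- panel$variants$eaf[col]
  freq_ok <- abs(sub$eaf - pan_eaf) <= freq_diff_max
  if (any(!freq_ok)) {
    log_lines <- c(log_lines,
                   sprintf("%d variant(s) excluded: |eaf - panel eaf| > %g",
                           sum(!freq_ok), freq_diff_max))
    sub <- sub[freq_ok, , drop = FALSE]
    col <- col[freq_ok]
  }
  poly <- apply(panel$dosages[, col, drop = FALSE], 2, stats::sd) > 0
  sub <- sub[poly, , drop = FALSE]
  col <- col[poly]
  m <- nrow(sub)
  if (m == 0) return(empty_signals(log_lines))

  n <- median(sub$n)
  f <- sub$eaf
  d <- if (var_from_panel) {
    apply(panel$dosages[, col, drop = FALSE], 2, var) * (n - 1)
  } else {
    2 * f * (1 - f) * n
  }
  yty <- if (trait_type(ss) == "quantitative") {
    sdy <- tryCatch(estimate_sdY(sub), error = function(e) 1)
    sdy^2 * (n - 1)
  } else {
    n - 1
  }
  R <- ld_matrix(panel, col)

  selected <- which.min(sub$p)
  if (sub$p[selected] >= p_joint_max) {
    # marginal lead itself not conditionally significant at the joint threshold
    fit <- joint_fit(sub$beta[selected], d[selected], matrix(1, 1, 1), yty, n)
    if (is.null(fit) || fit$p_joint >= p_joint_max) return(empty_signals(log_lines))
  }
  repeat {
    cand <- setdiff(seq_len(m), selected)
    if (length(cand) == 0) break
    collinear <- vapply(cand, function(j) any(R[j, selected]^2 >= r2_collinear),
                        logical(1))
    cand <- cand[!collinear]
    if (length(cand) == 0) break
    best_p <- Inf; best_j <- NA_integer_
    for (j in cand) {
      set <- c(selected, j)
      fit <- joint_fit(sub$beta[set], d[set], R[set, set, drop = FALSE], yty, n)
      if (is.null(fit)) {
        log_lines <- c(log_lines, sprintf("candidate %s:%d skipped: ill-conditioned LD",
                                          sub$chrom[j], sub$pos[j]))
        next
      }
      pj <- fit$p_joint[length(set)]
      if (pj < best_p) { best_p <- pj; best_j <- j }
    }
    if (is.na(best_j) || best_p >= p_joint_max) break
    selected <- c(selected, best_j)
  }
  # backward sweep: the final joint model must keep every signal significant
  repeat {
    fit <- joint_fit(sub$beta[selected], d[selected],
                     R[selected, selected, drop = FALSE], yty, n)
    if (is.null(fit)) {
      log_lines <- c(log_lines, "final joint LD matrix ill-conditioned; lead retained alone")
      selected <- selected[1]
      fit <- joint_fit(sub$beta[selected], d[selected], matrix(1, 1, 1), yty, n)
    }
    worst <- which.max(fit$p_joint)
    if (fit$p_joint[worst] < p_joint_max) break
    selected <- selected[-worst]
    if (length(selected) == 0) return(empty_signals(log_lines))
  }
  out <- dplyr::bind_cols(
    sub[selected, c("chrom", "pos", "ref", "alt", "eaf", "beta", "se", "p")],
    fit)
  out$conditional_on <- purrr::map(seq_along(selected), function(k) {
    sub$pos[selected[-k]]
  })
  structure(out[order(out$p_joint), ],
            class = c("gwas_signals", class(tibble())),
            log = log_lines)
}

empty_signals <- function(log_lines = character(0)) {
  structure(tibble(chrom = character(), pos = numeric(), ref = character(),
                   alt = character(), eaf = numeric(), beta = numeric(),
                   se = numeric(), p = numeric(), joint_beta = numeric(),
                   joint_se = numeric(), p_joint = numeric(),
                   conditional_on = list()),
            class = c("gwas_signals", class(tibble())),
            log = log_lines)
}

#' Read a BED-like gene table
#'
#' Tab-delimited with header columns `chrom`, `txStart`, `txEnd`, `strand`,
#' `name` (transcription start site = `txStart` on the + strand, `txEnd` on
#' the - strand).
#'
#' @param path File path.
#' @return A tibble of genes.
#' @export
read_gene_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), txStart = readr::col_double(),
    txEnd = readr::col_double(), strand = readr::col_character(),
    name = readr::col_character()), progress = FALSE)
}

#' Annotate positions with the nearest gene
#'
#' For each lead variant, the gene on the same chromosome minimising the
#' distance to its transcription start site; the distance is reported as 0
#' when the lead lies inside the gene body. Ties break by smaller TSS, then
#' lexicographic gene name. Chromosomes with no gene are annotated `NA`.
#'
#' @param signals A data frame with `chrom` and `pos` columns (e.g.
#'   [stepwise_conditional()] output).
#' @param genes A gene table from [read_gene_table()] (columns `chrom`,
#'   `txStart`, `txEnd`, `strand`, `name`).
#' @return `signals` with `nearest_gene` and `gene_distance` columns added.
#' @export
nearest_gene <- function(signals, genes) {
  genes <- as_tibble(genes)
  if (nrow(genes) == 0) abort("gene table is empty")
  tss <- ifelse(genes$strand == "-", genes$txEnd, genes$txStart)
  lo <- pmin(genes$txStart, genes$txEnd)
  hi <- pmax(genes$txStart, genes$txEnd)
  gchrom <- norm_chrom(genes$chrom)
  ann <- purrr::map(seq_len(nrow(signals)), function(i) {
    on_chr <- which(gchrom == norm_chrom(signals$chrom[i]))
    if (length(on_chr) == 0) {
      return(list(gene = NA_character_, dist = NA_real_))
    }
    pos <- signals$pos[i]
    dist <- ifelse(pos >= lo[on_chr] & pos <= hi[on_chr], 0,
                   abs(tss[on_chr] - pos))
    o <- order(dist, tss[on_chr], genes$name[on_chr])
    j <- on_chr[o[1]]
    list(gene = genes$name[j], dist = dist[o[1]])
  })
  signals$nearest_gene <- purrr::map_chr(ann, "gene")
  signals$gene_distance <- purrr::map_dbl(ann, "dist")
  signals
}
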