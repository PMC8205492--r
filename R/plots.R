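#' Regional association plot
#'
#' -log10(p) against position for one chromosome region, with optional locus
#' windows shaded and a significance threshold line.
#'
#' @param ss A `gwas_sumstats` object.
#' @param loci Optional [find_loci()] output to shade.
#' @param p_threshold Optional horizontal reference line.
#' @return A ggplot object.
#' @export
plot_region <- function(ss, loci = NULL, p_threshold = NULL) {
  df <- as_tibble(ss)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6,
                                         y = -log10(.data$p))) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p)),
                  title = trait_id(ss)) +
    ggplot2::theme_minimal()
  if (!is.null(loci) && nrow(loci) > 0) {
    gg <- gg + ggplot2::geom_rect(
      data = as_tibble(loci)[c("start", "end")],
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "steelblue")
  }
  if (!is.null(p_threshold)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(p_threshold),
                                   linetype = "dashed", colour = "red")
  }
  gg
}

#' @export
autoplot.gwas_sumstats <- function(object, ...) plot_region(object, ...)

#' Posterior mass plot for a credible set
#'
#' Renormalised per-variant posterior against position, with credible-set
#' members highlighted.
#'
#' @param object A `credible_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.credible_set <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6, y = .data$pi_renorm,
                                   colour = .data$in_set)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos / 1e6, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
                                 name = sprintf("in %.0f%% set", 100 * attr(object, "cutoff"))) +
    ggplot2::labs(x = "position (Mb)", y = "posterior probability (renormalised)") +
    ggplot2::theme_minimal()
}

#' Posterior bar plot for a colocalisation result
#'
#' @param object A `coloc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coloc_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hypothesis, y = .data$posterior)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.99, linetype = "dashed", colour = "grey40") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "posterior probability",
                  title = paste("decision:", object$decision)) +
    ggplot2::theme_minimal()
}
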