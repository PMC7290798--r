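#' Plot PCA scores
#'
#' Score plot of the first two components, coloured by sample role and
#' biological group — the standard visual check that pooled-QC injections
#' cluster tightly inside the biological spread.
#'
#' @param object A `metab_pca` from [pca_scores()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metab_pca <- function(object, ...) {
  sc <- object$scores
  sc$label <- ifelse(sc$role == "biological", sc$group, sc$role)
  ggplot2::ggplot(sc, ggplot2::aes(
    x = .data$PC1, y = .data$PC2,
    colour = .data$label, shape = .data$role
  )) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2]),
      colour = NULL, shape = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential result
#'
#' log2 fold change against -log10 p, with the significance window drawn:
#' features outside the fold-change band and below the p threshold are
#' highlighted.
#'
#' @param object A `metab_diff` from [run_differential()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metab_diff <- function(object, ...) {
  cfg <- attr(object, "config")
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$log2_fc, y = -log10(.data$p_value),
    colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::geom_vline(
      xintercept = log2(c(cfg$fc_low, cfg$fc_high)), linetype = "dashed"
    ) +
    ggplot2::geom_hline(yintercept = -log10(cfg$alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey60")
    ) +
    ggplot2::labs(
      title = object$contrast[1],
      x = "log2 fold change", y = "-log10 p", colour = "significant"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-feature pooled-QC RSD
#'
#' Histogram of QC relative standard deviations with the filter threshold
#' marked.
#'
#' @param mt A [metab_table()] containing QC samples.
#' @param max_rsd_pct Threshold line (default 30).
#' @return A ggplot.
#' @export
plot_qc_rsd <- function(mt, max_rsd_pct = 30) {
  rsd <- qc_rsd_values(mt)
  d <- tibble::tibble(rsd = rsd[is.finite(rsd)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rsd)) +
    ggplot2::geom_histogram(bins = 50, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = max_rsd_pct, linetype = "dashed") +
    ggplot2::labs(x = "pooled-QC RSD (%)", y = "features") +
    ggplot2::theme_minimal()
}
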