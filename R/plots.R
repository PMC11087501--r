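# ggplot2 views of the main result types.

#' Box plot of relative X expression by group
#'
#' @param object an `rxe_table` from [compute_rxe()].
#' @param by grouping column for the x axis (default `"sex"`).
#' @param facet optional faceting column (default `"region"` when present).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rxe_table <- function(object, by = "sex",
                               facet = if ("region" %in% names(object)) "region" else NULL,
                               ...) {
  check_columns(object, c("rxe", by), "RXE table")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data[[by]], y = .data$rxe,
                                            fill = .data[[by]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6, alpha = 0.8) +
    ggplot2::labs(x = NULL, y = "relative X expression (log2)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
  if (!is.null(facet)) p <- p + ggplot2::facet_wrap(facet)
  p
}

#' Volcano plot of a differential-expression result
#'
#' @param de a `moderated_fit` or tidied DE table.
#' @param fdr_cutoff highlighting threshold (default 0.05).
#' @return a ggplot.
#' @export
plot_volcano <- function(de, fdr_cutoff = 0.05) {
  tab <- if (inherits(de, "moderated_fit")) de$table else de
  check_columns(tab, c("logFC", "P.Value", "adj.P.Val"), "DE table")
  tab$signif <- !is.na(tab$adj.P.Val) & tab$adj.P.Val < fdr_cutoff
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$logFC,
                                    y = -log10(.data$P.Value),
                                    colour = .data$signif)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = sprintf("FDR < %g", fdr_cutoff)) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Effect-size concordance scatter for two DE analyses
#'
#' @param de_a,de_b `moderated_fit`s or tidied DE tables.
#' @return a ggplot of shared-feature logFCs with the identity line.
#' @export
plot_concordance <- function(de_a, de_b) {
  a <- if (inherits(de_a, "moderated_fit")) de_a$table else de_a
  b <- if (inherits(de_b, "moderated_fit")) de_b$table else de_b
  m <- dplyr::inner_join(a, b, by = "feature_id", suffix = c("_a", "_b"))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$logFC_a, y = .data$logFC_b)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "steelblue") +
    ggplot2::labs(x = "log2FC (A)", y = "log2FC (B)") +
    ggplot2::theme_minimal()
}

#' Histogram of the subsampling null with the observed count
#'
#' @param x a `subsample_null`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.subsample_null <- function(x, ...) {
  ggplot2::ggplot(tidy(x), ggplot2::aes(x = .data$deg_count)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = x$observed, colour = "firebrick",
                        linetype = 2) +
    ggplot2::labs(x = "subsampled male DEG count",
                  y = "draws",
                  subtitle = sprintf("observed = %d, two-sided p = %.3g",
                                     x$observed, x$p_two_sided)) +
    ggplot2::theme_minimal()
}
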