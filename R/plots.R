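#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot trait effect sizes and significance across segments
#'
#' Bar chart of per-segment contrast effect sizes, colored by nominal
#' permutation significance.
#'
#' @param object An [fit_traits()] result.
#' @param alpha Significance level for the coloring.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.endo_traits <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  df$significant <- df$p_perm < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$segment_id), y = .data$r2,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "facial segment", y = expression(R^2),
                  fill = sprintf("p < %.2g", alpha)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 6))
}

#' Plot a PRS threshold scan
#'
#' The usual PRSice-style display: -log10 association p against -log10
#' inclusion threshold, one line per trait, with an optional significance
#' line at `alpha / m_eff`.
#'
#' @param object An [prs_scan()] result.
#' @param signif_line Optional p-value to draw as a horizontal reference.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.endo_prs_scan <- function(object, signif_line = NULL, ...) {
  g <- ggplot2::ggplot(object,
                       ggplot2::aes(x = -log10(.data$threshold),
                                    y = -log10(.data$p),
                                    color = .data$trait)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(-log[10] ~ "inclusion threshold"),
                  y = expression(-log[10] ~ italic(p))) +
    ggplot2::theme_minimal()
  if (!is.null(signif_line))
    g <- g + ggplot2::geom_hline(yintercept = -log10(signif_line),
                                 linetype = "dashed")
  g
}

#' Manhattan-style plot of meta-analyzed associations
#'
#' @param meta A [meta_scans()] table.
#' @param genomewide,studywide Threshold lines to draw.
#' @return A ggplot.
#' @export
plot_manhattan <- function(meta, genomewide = 5e-8, studywide = NULL) {
  g <- ggplot2::ggplot(meta, ggplot2::aes(x = .data$pos, y = -log10(.data$p),
                                          color = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::geom_hline(yintercept = -log10(genomewide), linetype = "dashed") +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10] ~ italic(p))) +
    ggplot2::theme_minimal()
  if (!is.null(studywide))
    g <- g + ggplot2::geom_hline(yintercept = -log10(studywide),
                                 linetype = "dotted")
  g
}
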