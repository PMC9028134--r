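# ggplot2 visualizations of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot outlier calls against their null band
#'
#' Scatter of clr coordinates with the orthogonal best-fit line and the
#' nontoxin band; outliers highlighted.
#'
#' @param object An `outlier_calls` tibble from [call_outliers()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot outlier_calls
#' @export
autoplot.outlier_calls <- function(object, ...) {
  band <- attr(object, "band")
  w <- band$half_width * sqrt(1 + band$fit$slope^2)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = band$fit$slope,
                         intercept = band$fit$intercept, colour = "steelblue") +
    ggplot2::geom_abline(slope = band$fit$slope,
                         intercept = band$fit$intercept + c(-w, w),
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_outlier)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "clr expression (axis 1)", y = "clr expression (axis 2)",
                  colour = "outlier") +
    ggplot2::theme_minimal()
}

#' Plot a transcriptome-proteome correlation
#'
#' Scatter of protein vs transcript clr with the identity line (solid) and
#' the best-fit line (dashed).
#'
#' @param object An `omics_correlation` from [correlate_omics()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot omics_correlation
#' @export
autoplot.omics_correlation <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$clr_transcript, y = .data$clr_protein)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "black") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::labs(
      x = "transcriptome clr", y = "proteome clr",
      subtitle = sprintf("rho = %.2f, R = %.2f, n = %d",
                         object$rho, object$r, object$n)) +
    ggplot2::theme_minimal()
}

#' Bar chart of toxin family composition per species
#'
#' @param summary A [compose_family_summary()] tibble.
#' @return A ggplot.
#' @export
plot_family_composition <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = stats::reorder(.data$family, -.data$pct),
                               y = .data$pct, fill = .data$species)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "toxin family", y = "% of toxin expression",
                  fill = "species") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Boxplots of dN/dS metrics for toxins versus nontoxins
#'
#' @param results A [pairwise_dnds()] tibble with `class` and `filter_flag`.
#' @param comparison Optional [compare_groups()] result; adds its
#'   95th-percentile thresholds as dashed lines.
#' @return A ggplot.
#' @export
plot_dnds_groups <- function(results, comparison = NULL) {
  res <- results[results$filter_flag == "pass", , drop = FALSE]
  res$group <- ifelse(res$class == "nontoxin", "nontoxin", "toxin")
  long <- tidyr::pivot_longer(res[c("group", "dS", "dN", "omega")],
                              c("dS", "dN", "omega"),
                              names_to = "metric", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                          fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
  if (!is.null(comparison)) {
    thr <- tidy(comparison)
    thr$metric <- thr$metric
    p <- p + ggplot2::geom_hline(data = thr,
                                 ggplot2::aes(yintercept = .data$threshold),
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}
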