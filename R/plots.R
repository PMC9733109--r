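# Diagnostic figures for the three result types.

#' @describeIn pca_counts Scatter of the first two principal components;
#'   pass `groups` (named by individual) to colour points.
#' @param object A `counts_pca` object.
#' @param groups Optional named vector mapping individuals to groups.
#' @export
autoplot.counts_pca <- function(object, groups = NULL, ...) {
  df <- tidy(object)
  df$group <- if (!is.null(groups)) unname(groups[df$individual_id]) else "all"
  ve <- object$var_explained
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2]),
      colour = NULL) +
    ggplot2::theme_minimal()
}

#' Boxplots of compartment use per population
#'
#' @param x A `cage_use` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cage_use <- function(x, ...) {
  long <- tidyr::pivot_longer(x$proportions,
                              c("home", "neutral", "foreign", "tube", "water_escape"),
                              names_to = "compartment", values_to = "proportion")
  long$compartment <- factor(long$compartment,
                             c("home", "neutral", "foreign", "tube", "water_escape"))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$compartment, .data$proportion))
  if (!all(is.na(long$population))) {
    p <- p + ggplot2::geom_boxplot(ggplot2::aes(fill = .data$population))
  } else {
    p <- p + ggplot2::geom_boxplot()
  }
  p + ggplot2::labs(x = NULL, y = "visit proportion") + ggplot2::theme_minimal()
}

#' Log-scale boxplots of the enclosure movement metrics
#'
#' Mirrors the usual four-panel view: touch and cross latency, passages and
#' foreign-arena time, log(x+1) transformed, split by population.
#'
#' @param metrics Output of [rfid_metrics()].
#' @return A ggplot.
#' @export
plot_metrics <- function(metrics) {
  long <- tidyr::pivot_longer(
    metrics,
    c("touch_latency_s", "cross_latency_s", "n_passages", "time_foreign_h"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(stats::na.omit(long[, c("population", "metric", "value")]),
                  ggplot2::aes(.data$population, log1p(.data$value),
                               fill = .data$population)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "log(1 + value)") +
    ggplot2::theme_minimal()
}
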