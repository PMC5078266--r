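#' Plot coefficient-of-variation curves across thresholds
#'
#' One CV curve per binarized-graph metric, with the cohort mean weighted
#' density marked: thresholds to its right are rejected by
#' [select_threshold()].
#'
#' @param object A `threshold_scan` from [metric_cv_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.threshold_scan <- function(object, ...) {
  dens <- attr(object, "mean_density")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$tau, y = .data$cv,
                               colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = dens, linetype = "dashed") +
    ggplot2::labs(x = expression(tau), y = "Coefficient of variation",
                  colour = "Metric",
                  subtitle = sprintf("dashed line: mean weighted density = %.2f",
                                     dens)) +
    ggplot2::theme_minimal()
}

#' Plot density against the number of sampled streamlines
#'
#' Mean weighted-graph density with a +/- 1 SD ribbon over the fiber grid
#' (log scale), showing where density saturates.
#'
#' @param object A `fiber_scan` from [density_vs_fibers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fiber_scan <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$f, y = .data$mean_density)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_density - .data$sd_density,
      ymax = .data$mean_density + .data$sd_density
    ), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Number of fibers f", y = "Mean weighted density") +
    ggplot2::theme_minimal()
}

#' Box plots of the six global metrics by group
#'
#' @param metrics Metric table from [connectome_metrics()].
#' @return A ggplot object (one free-scaled facet per metric).
#' @export
plot_metric_distributions <- function(metrics) {
  long <- tidyr::pivot_longer(metrics, dplyr::all_of(METRIC_COLS),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, levels = METRIC_COLS)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-class precision, recall and F-measure of a classification task
#'
#' @param object A `classification_report` from [run_task()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.classification_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_class[, c("class", "precision", "recall", "f_measure")],
    -"class", names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("Task %s (%s features)", object$task,
                                  object$feature_set),
                  x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
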