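# ggplot2 views of the main result types.

#' Plot a ranked hit table
#'
#' Surfaces ordered by rank with their positive fraction, coloured by class,
#' with the flat-reference fraction as a dashed line.
#'
#' @param object A `topo_hit_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.topo_hit_table <- function(object, ...) {
  meta <- attr(object, "hit_meta")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$pos_fraction,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = meta$ref_fraction, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(High = "#D55E00", Low = "#0072B2", NS = "grey60")) +
    ggplot2::labs(x = "surface rank", y = "marker-positive fraction",
                  colour = NULL,
                  title = "Surfaces ranked by marker-positive cell fraction",
                  subtitle = sprintf("dashed: flat-well reference (%.3f)",
                                     meta$ref_fraction)) +
    ggplot2::theme_minimal()
}

#' Plot a model report
#'
#' Held-out accuracies over repeats (histogram) are summarised in the
#' subtitle; bars show permutation importance mean with one-sd error bars.
#'
#' @param object A `topo_model_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.topo_model_report <- function(object, ...) {
  imp <- object$importance
  imp$feature <- factor(imp$feature, levels = rev(imp$feature))
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$importance_mean,
                                    y = .data$feature)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$importance_mean - .data$importance_sd,
                   xmax = .data$importance_mean + .data$importance_sd),
      height = 0.25) +
    ggplot2::labs(x = "permutation importance (held-out accuracy drop)",
                  y = NULL,
                  title = "Feature importance over repeated splits",
                  subtitle = sprintf(
                    "mean held-out accuracy %.3f (sd %.3f) over %d repeats",
                    object$mean_accuracy, sd(object$accuracies),
                    length(object$accuracies))) +
    ggplot2::theme_minimal()
}

#' Plot control intensity distributions with the calibrated threshold
#'
#' @param controls Controls tibble (`condition`, `icam1_median_intensity`).
#' @param calibration Optional `threshold_calibration`; drawn as a vertical
#'   line at the crossing.
#' @return A ggplot object.
#' @export
plot_control_densities <- function(controls, calibration = NULL) {
  check_columns(controls, c("condition", "icam1_median_intensity"),
                "controls")
  p <- ggplot2::ggplot(controls,
                       ggplot2::aes(x = .data$icam1_median_intensity,
                                    fill = .data$condition)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_manual(
      values = c(neg = "#0072B2", pos = "#D55E00"),
      labels = c(neg = "negative control", pos = "stimulated control")) +
    ggplot2::labs(x = "per-cell median marker intensity (a.u., log scale)",
                  y = "density", fill = NULL,
                  title = "Control intensity distributions") +
    ggplot2::theme_minimal()
  if (!is.null(calibration)) {
    p <- p + ggplot2::geom_vline(xintercept = calibration$threshold,
                                 colour = "red") +
      ggplot2::labs(subtitle = sprintf(
        "crossing at %.3g a.u. = %.1fth percentile of the negative control",
        calibration$threshold, calibration$calibration_percentile))
  }
  p
}

#' Plot per-chip well cell-count distributions
#'
#' @param summary A `screen_summary` from [summarize_screen()], or a well
#'   index tibble with `chip_id` and `n_cells`.
#' @return A ggplot object.
#' @export
plot_well_counts <- function(summary) {
  wells <- if (inherits(summary, "screen_summary")) {
    abort("pass the wells tibble (`dataset$wells`), not the summary.")
  } else summary
  check_columns(wells, c("chip_id", "n_cells"), "wells")
  ggplot2::ggplot(wells, ggplot2::aes(x = .data$n_cells)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey35") +
    ggplot2::facet_wrap(~chip_id) +
    ggplot2::labs(x = "cells per well", y = "wells",
                  title = "Cell count per well by chip replica") +
    ggplot2::theme_minimal()
}
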