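#' Calibrate the positivity percentile from control distributions
#'
#' Fits kernel-density estimates to the negative and positive control
#' intensity samples (on the log scale, where lognormal components are
#' symmetric) and finds the lowest-intensity crossing point of the two
#' densities inside the overlap region. The returned calibration percentile
#' is the rank of that crossing point within the negative-control sample;
#' with the default synthetic components it lands at the 93rd percentile.
#'
#' @param neg,pos Numeric vectors of per-cell median intensities, or `neg`
#'   may be a controls tibble with columns `condition` (`"neg"`/`"pos"`) and
#'   `icam1_median_intensity`.
#' @param min_cells Minimum sample size per condition (default 100).
#' @param grid_n Density grid resolution.
#' @return An object of class `threshold_calibration`: list with
#'   `calibration_percentile`, `threshold` (the crossing intensity, a.u.),
#'   `method = "control_intersection"`, and the evaluated density grid.
#' @export
calibrate_threshold <- function(neg, pos = NULL, min_cells = 100,
                                grid_n = 512) {
  if (is.data.frame(neg)) {
    check_columns(neg, c("condition", "icam1_median_intensity"), "controls")
    pos <- neg$icam1_median_intensity[neg$condition == "pos"]
    neg <- neg$icam1_median_intensity[neg$condition == "neg"]
  }
  if (length(neg) < min_cells || length(pos) < min_cells) {
    abort(sprintf("need at least %d cells per control condition.", min_cells),
          class = "toposcreen_config_error")
  }
  if (any(c(neg, pos) <= 0)) {
    abort("intensities must be positive.", class = "toposcreen_config_error")
  }
  ln <- log(neg); lp <- log(pos)
  lo <- max(min(ln), min(lp))
  hi <- min(max(ln), max(lp))
  if (lo >= hi) {
    abort("no intersection in overlap: control supports are disjoint.",
          class = "toposcreen_calibration_error")
  }
  dn <- density(ln, n = grid_n)
  dp <- density(lp, n = grid_n)
  grid <- seq(lo, hi, length.out = grid_n)
  fn <- approx(dn$x, dn$y, grid, rule = 2)$y
  fp <- approx(dp$x, dp$y, grid, rule = 2)$y
  diff <- fn - fp
  if (max(abs(diff)) < 1e-3 * max(fn, fp)) {
    abort("no unique intersection: control distributions are identical.",
          class = "toposcreen_calibration_error")
  }
  sign_change <- which(diff[-length(diff)] * diff[-1] < 0 |
                         (diff[-length(diff)] != 0 & diff[-1] == 0))
  if (length(sign_change) == 0) {
    abort("no intersection in overlap: densities do not cross.",
          class = "toposcreen_calibration_error")
  }
  i <- sign_change[1]
  # linear interpolation of the crossing between grid points
  x0 <- grid[i]; x1 <- grid[i + 1]
  w <- diff[i] / (diff[i] - diff[i + 1])
  crossing_log <- x0 + w * (x1 - x0)
  threshold <- exp(crossing_log)
  pct <- 100 * mean(neg <= threshold)
  if (pct > 99) {
    warn(sprintf(
      "calibration percentile %.2f > 99: controls barely overlap.", pct))
  }
  structure(list(calibration_percentile = pct, threshold = threshold,
                 method = "control_intersection",
                 grid = tibble::tibble(log_intensity = grid,
                                       dens_neg = fn, dens_pos = fp),
                 n_neg = length(neg), n_pos = length(pos)),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf(
    "<threshold_calibration> crossing at %.3g a.u. = percentile %.2f of the negative control\n",
    x$threshold, x$calibration_percentile))
  invisible(x)
}

#' Apply the adaptive per-chip intensity threshold
#'
#' For each chip the positivity cutoff is the `percentile`-th percentile
#' (linear-interpolation, type-7 quantile) of that chip's own post-QC
#' intensity distribution; a cell is positive when its intensity exceeds the
#' cutoff strictly. Per construction each chip flags a fraction of about
#' `1 - percentile/100` of its cells, which absorbs chip-to-chip intensity
#' scaling (batch effects).
#'
#' @param cells Per-cell tibble with `chip_id` and `icam1_median_intensity`.
#' @param percentile The calibration percentile (default 93), or a
#'   `threshold_calibration` object.
#' @param min_cells_per_chip Chips with fewer cells raise an error (the
#'   percentile is unstable; default 50).
#' @return `cells` with an added logical column `icam1_positive`; the
#'   per-chip cutoffs are attached as attribute `thresholds` (tibble
#'   `chip_id`, `threshold`, `n_cells`) and the percentile as attribute
#'   `calibration_percentile`.
#' @export
apply_threshold <- function(cells, percentile = 93, min_cells_per_chip = 50) {
  if (inherits(percentile, "threshold_calibration")) {
    percentile <- percentile$calibration_percentile
  }
  check_columns(cells, c("chip_id", "icam1_median_intensity"), "cells")
  if (percentile <= 0 || percentile >= 100) {
    abort("`percentile` must be in (0, 100).",
          class = "toposcreen_config_error")
  }
  thr <- cells |>
    dplyr::group_by(.data$chip_id) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     threshold = quantile(.data$icam1_median_intensity,
                                          percentile / 100, type = 7,
                                          names = FALSE),
                     .groups = "drop")
  low <- thr$chip_id[thr$n_cells < min_cells_per_chip]
  if (length(low) > 0) {
    abort(sprintf("chip `%s` has fewer than %d cells; percentile unstable.",
                  low[[1]], min_cells_per_chip),
          class = "toposcreen_config_error")
  }
  cutoff <- setNames(thr$threshold, thr$chip_id)
  out <- dplyr::mutate(cells,
    icam1_positive = .data$icam1_median_intensity > cutoff[.data$chip_id])
  attr(out, "thresholds") <- thr
  attr(out, "calibration_percentile") <- percentile
  out
}

#' Per-chip thresholds of a flagged cell table
#'
#' @param cells Output of [apply_threshold()].
#' @return The `thresholds` attribute tibble.
#' @export
chip_thresholds <- function(cells) {
  thr <- attr(cells, "thresholds")
  if (is.null(thr)) {
    abort("`cells` carries no thresholds; run apply_threshold() first.",
          class = "toposcreen_config_error")
  }
  thr
}
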