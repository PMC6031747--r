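#' Summary statistics of a flagged screen
#'
#' Convenience summaries mirroring the screen-level readouts: per-chip
#' median cells per well (including empty wells), per-surface pooled cell
#' counts, a Wilcoxon rank-sum comparison of per-cell marker intensities on
#' topographies versus on-chip flat wells, and the Pearson correlation of
#' log actin with log marker intensity.
#'
#' @param cells Flagged cell table (post QC and [apply_threshold()]).
#' @param hits A `topo_hit_table` from [call_hits()].
#' @param layout The chip layout.
#' @param n_chips Number of chips; defaults to those present in `cells`.
#' @return A list of class `screen_summary`.
#' @export
summarize_screen <- function(cells, hits, layout, n_chips = NULL) {
  meta <- attr(layout, "layout_meta")
  flat_id <- meta$flat_id
  chips <- sort(unique(cells$chip_id))
  n_chips <- n_chips %||% length(chips)

  # well index including zero-cell wells
  well_counts <- tidyr::expand_grid(
    chip_id = chips,
    tibble::as_tibble(layout[c("row", "col", "unit_id")])) |>
    dplyr::left_join(
      dplyr::count(cells, .data$chip_id, .data$row, .data$col,
                   name = "n_cells"),
      by = c("chip_id", "row", "col")) |>
    dplyr::mutate(n_cells = dplyr::coalesce(.data$n_cells, 0L))

  per_chip <- well_counts |>
    dplyr::group_by(.data$chip_id) |>
    dplyr::summarise(median_cells_per_well = median(.data$n_cells),
                     n_cells = sum(.data$n_cells), .groups = "drop")

  per_surface <- well_counts |>
    dplyr::filter(.data$unit_id != flat_id) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(pooled_cells = sum(.data$n_cells),
                     n_wells = dplyr::n(), .groups = "drop")

  topo_int <- cells$icam1_median_intensity[cells$unit_id != flat_id]
  flat_int <- cells$icam1_median_intensity[cells$unit_id == flat_id]
  wt <- if (length(topo_int) > 0 && length(flat_int) > 0) {
    suppressWarnings(wilcox.test(topo_int, flat_int))
  } else NULL

  actin_r <- if ("actin_intensity" %in% names(cells)) {
    cor(log(cells$actin_intensity), log(cells$icam1_median_intensity))
  } else NA_real_

  structure(list(
    per_chip = per_chip,
    per_surface = per_surface,
    median_pooled_cells = median(per_surface$pooled_cells),
    intensity_topo_vs_flat = list(
      median_topo = median(topo_int),
      median_flat = if (length(flat_int)) median(flat_int) else NA_real_,
      p_value = if (!is.null(wt)) wt$p.value else NA_real_),
    actin_icam1_log_pearson = actin_r,
    hit_counts = as.list(table(hits$class)),
    n_chips = n_chips),
    class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<screen_summary> %d chips; per-chip median %s cells/well; ",
           "median pooled cells/surface %.0f\n",
           "  hits: %d High / %d Low / %d NS; topo vs flat rank-sum p = %.3g; ",
           "log actin~marker r = %.3f\n"),
    x$n_chips,
    paste(x$per_chip$median_cells_per_well, collapse = ","),
    x$median_pooled_cells,
    x$hit_counts$High, x$hit_counts$Low, x$hit_counts$NS,
    x$intensity_topo_vs_flat$p_value, x$actin_icam1_log_pearson))
  invisible(x)
}

# JSON-serializable view used by the pipeline writer
summary_as_list <- function(x) {
  list(
    n_chips = x$n_chips,
    per_chip_median_cells_per_well =
      setNames(as.list(x$per_chip$median_cells_per_well), x$per_chip$chip_id),
    median_pooled_cells_per_surface = x$median_pooled_cells,
    intensity_topo_vs_flat = x$intensity_topo_vs_flat,
    actin_icam1_log_pearson = x$actin_icam1_log_pearson,
    hit_counts = x$hit_counts)
}
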