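#' Quality-control filtering of per-cell records
#'
#' Flags probable mis-segmentations: a cell is excluded when its area or its
#' perimeter lies strictly outside `median +/- multiplier * IQR`, where the
#' median and IQR are computed over all cells of all replicas of that cell's
#' unique surface. Cells exactly on a bound are retained. Surfaces with fewer
#' than `min_cells` cells pass unfiltered and are flagged (quartiles are not
#' stable there).
#'
#' @param cells A per-cell tibble with `unit_id`, `area_um2`, `perimeter_um`
#'   and `cell_id` columns.
#' @param multiplier IQR multiplier (default 1.5).
#' @param min_cells Minimum per-surface cell count for filtering (default 4).
#' @return A list of class `topo_qc` with elements `cells` (the retained
#'   rows), `flags` (per-cell pass flags), `bounds` (per-surface exclusion
#'   bounds), `n_in`, `n_excluded`.
#' @export
#' @examples
#' cells <- tibble::tibble(unit_id = "u1", cell_id = as.character(1:6),
#'                         area_um2 = c(100, 101, 99, 100, 102, 1000),
#'                         perimeter_um = 40)
#' qc_filter(cells)$n_excluded
qc_filter <- function(cells, multiplier = 1.5, min_cells = 4) {
  check_columns(cells, c("unit_id", "area_um2", "perimeter_um", "cell_id"),
                "cells")
  bad <- which(!is.finite(cells$area_um2) | !is.finite(cells$perimeter_um))
  if (length(bad) > 0) {
    abort(sprintf("cell `%s` has a missing area or perimeter.",
                  cells$cell_id[bad[1]]), class = "toposcreen_schema_error")
  }
  bounds <- cells |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      area_med = median(.data$area_um2),
      area_iqr = IQR(.data$area_um2),
      perim_med = median(.data$perimeter_um),
      perim_iqr = IQR(.data$perimeter_um),
      .groups = "drop") |>
    dplyr::mutate(
      small_group = .data$n_cells < min_cells,
      area_lo = .data$area_med - multiplier * .data$area_iqr,
      area_hi = .data$area_med + multiplier * .data$area_iqr,
      perim_lo = .data$perim_med - multiplier * .data$perim_iqr,
      perim_hi = .data$perim_med + multiplier * .data$perim_iqr)

  flagged <- cells |>
    dplyr::left_join(
      bounds[c("unit_id", "small_group", "area_lo", "area_hi",
               "perim_lo", "perim_hi")], by = "unit_id") |>
    dplyr::mutate(qc_pass = .data$small_group |
      (.data$area_um2 >= .data$area_lo & .data$area_um2 <= .data$area_hi &
       .data$perimeter_um >= .data$perim_lo &
       .data$perimeter_um <= .data$perim_hi))

  structure(list(
    cells = cells[flagged$qc_pass, , drop = FALSE],
    flags = tibble::tibble(cell_id = cells$cell_id,
                           qc_pass = flagged$qc_pass),
    bounds = bounds[c("unit_id", "n_cells", "small_group", "area_lo",
                      "area_hi", "perim_lo", "perim_hi")],
    n_in = nrow(cells),
    n_excluded = sum(!flagged$qc_pass),
    multiplier = multiplier, min_cells = min_cells),
    class = "topo_qc")
}

#' @export
print.topo_qc <- function(x, ...) {
  cat(sprintf("<topo_qc> %d cells in, %d excluded (%.2f%%), %d surfaces\n",
              x$n_in, x$n_excluded, 100 * x$n_excluded / max(x$n_in, 1),
              nrow(x$bounds)))
  invisible(x)
}

#' @export
glance.topo_qc <- function(x, ...) {
  tibble::tibble(n_in = x$n_in, n_excluded = x$n_excluded,
                 fraction_excluded = x$n_excluded / max(x$n_in, 1),
                 n_surfaces = nrow(x$bounds),
                 n_small_groups = sum(x$bounds$small_group))
}
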