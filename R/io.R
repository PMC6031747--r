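# Readers and writers for the pipeline's file formats. CSV dialect: UTF-8,
# comma, header row, dot decimal regardless of locale; grid coordinates are
# 0-based with row 0 at the chip top.

cells_required_cols <- c("chip_id", "row", "col", "unit_id", "cell_id",
                         "area_um2", "perimeter_um", "form_factor",
                         "solidity", "eccentricity", "median_radius_um",
                         "icam1_median_intensity", "actin_intensity")

hit_table_cols <- c("unit_id", "n_cells", "n_pos", "pos_fraction",
                    "chi2_stat", "p_value", "p_adj", "class", "rank")

# Deterministic CSV writer: doubles are rendered with 15 significant digits,
# which reparse to the printed value and re-render identically, so
# write -> read -> write is byte-stable.
write_csv_stable <- function(df, path) {
  num <- vapply(df, is.double, NA)
  df[num] <- lapply(df[num], function(x) {
    out <- sprintf("%.15g", x)
    out[is.na(x)] <- NA_character_
    out
  })
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

stop_on_parse_problems <- function(df, path) {
  pr <- readr::problems(df)
  if (nrow(pr) > 0) {
    abort(sprintf("parse error in %s at row %d, column `%s`: expected %s.",
                  path, pr$row[1], as.character(pr$col[1]), pr$expected[1]),
          class = "toposcreen_schema_error")
  }
  df
}

#' Read / write the per-cell table
#'
#' Canonical columns first, any extra columns preserved; numeric parsing is
#' locale-independent (dot decimal). Unknown columns round-trip unchanged.
#'
#' @param path CSV path.
#' @param cells Per-cell tibble.
#' @return `read_cells()` a tibble; `write_cells()` the path, invisibly.
#' @export
read_cells <- function(path) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  check_columns(stats::setNames(data.frame(matrix(ncol = length(header),
                                                  nrow = 0)), header),
                cells_required_cols, basename(path))
  types <- readr::cols(
    chip_id = readr::col_character(), unit_id = readr::col_character(),
    cell_id = readr::col_character(),
    row = readr::col_integer(), col = readr::col_integer(),
    area_um2 = readr::col_double(), perimeter_um = readr::col_double(),
    form_factor = readr::col_double(), solidity = readr::col_double(),
    eccentricity = readr::col_double(),
    median_radius_um = readr::col_double(),
    icam1_median_intensity = readr::col_double(),
    actin_intensity = readr::col_double())
  df <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = types,
                    locale = readr::locale(decimal_mark = ".")))
  stop_on_parse_problems(df, path)
  df
}

#' @rdname read_cells
#' @export
write_cells <- function(cells, path) {
  check_columns(cells, setdiff(cells_required_cols, "actin_intensity"),
                "cells")
  extra <- setdiff(names(cells), cells_required_cols)
  keep <- c(intersect(cells_required_cols, names(cells)), extra)
  write_csv_stable(cells[keep], path)
}

#' Read / write control samples
#'
#' @param controls Tibble with `condition`, `cell_id`,
#'   `icam1_median_intensity`.
#' @param path CSV path.
#' @export
read_controls <- function(path) {
  df <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(
                      condition = readr::col_character(),
                      cell_id = readr::col_character(),
                      icam1_median_intensity = readr::col_double())))
  stop_on_parse_problems(df, path)
  check_columns(df, c("condition", "cell_id", "icam1_median_intensity"),
                basename(path))
  if (!all(df$condition %in% c("neg", "pos"))) {
    abort(sprintf("%s: `condition` must be 'neg' or 'pos'.", basename(path)),
          class = "toposcreen_schema_error")
  }
  df
}

#' @rdname read_controls
#' @export
write_controls <- function(controls, path) {
  check_columns(controls, c("condition", "cell_id", "icam1_median_intensity"),
                "controls")
  write_csv_stable(controls, path)
}

#' Read / write a chip layout
#'
#' The layout is a headerless TSV of unit ids (one row per grid row) with a
#' JSON sidecar (`<path>.meta.json`) carrying the well geometry metadata.
#'
#' @param layout A `chip_layout`.
#' @param path TSV path.
#' @export
write_layout <- function(layout, path) {
  grid <- layout_grid(layout)
  readr::write_tsv(as.data.frame(grid), path, col_names = FALSE,
                   progress = FALSE)
  meta <- attr(layout, "layout_meta")
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    abort(sprintf("layout sidecar %s not found.", meta_path),
          class = "toposcreen_schema_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  grid <- as.matrix(readr::read_tsv(path, col_names = FALSE,
                                    col_types = readr::cols(
                                      .default = readr::col_character()),
                                    progress = FALSE))
  if (nrow(grid) != meta$n_rows || ncol(grid) != meta$n_cols) {
    abort(sprintf("layout grid is %d x %d but sidecar declares %d x %d.",
                  nrow(grid), ncol(grid), meta$n_rows, meta$n_cols),
          class = "toposcreen_schema_error")
  }
  out <- tibble::tibble(
    row = rep(seq_len(meta$n_rows) - 1L, each = meta$n_cols),
    col = rep(seq_len(meta$n_cols) - 1L, times = meta$n_rows),
    unit_id = as.vector(t(grid)))
  class(out) <- c("chip_layout", class(out))
  attr(out, "layout_meta") <- meta
  out
}

#' Read / write a hit table
#'
#' The file carries exactly the canonical columns; class attributes and
#' reference metadata live in memory only.
#'
#' @param hits A `topo_hit_table`.
#' @param path CSV path.
#' @export
write_hit_table <- function(hits, path) {
  check_columns(hits, hit_table_cols, "hit table")
  out <- tibble::as_tibble(hits)[hit_table_cols]
  out$class <- as.character(out$class)
  write_csv_stable(out, path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  df <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(
                      unit_id = readr::col_character(),
                      n_cells = readr::col_integer(),
                      n_pos = readr::col_integer(),
                      pos_fraction = readr::col_double(),
                      chi2_stat = readr::col_double(),
                      p_value = readr::col_double(),
                      p_adj = readr::col_double(),
                      class = readr::col_character(),
                      rank = readr::col_integer())))
  stop_on_parse_problems(df, path)
  check_columns(df, hit_table_cols, basename(path))
  df$class <- factor(df$class, levels = c("High", "Low", "NS"))
  class(df) <- c("topo_hit_table", class(df))
  df
}

#' Write a screen dataset to a directory
#'
#' Emits `cells.csv`, `controls.csv`, `wells.csv` (per-well index including
#' zero-cell wells), `layout.tsv` (+ metadata sidecar) and
#' `provenance.json` with the full generator configuration and seeds; the
#' dataset can be reproduced bit-identically from the provenance.
#'
#' @param ds A `screen_dataset` from [simulate_screen()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_screen_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "screen_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cells(ds$cells, file.path(dir, "cells.csv"))
  write_controls(ds$controls, file.path(dir, "controls.csv"))
  readr::write_csv(ds$wells, file.path(dir, "wells.csv"), progress = FALSE)
  write_layout(ds$layout, file.path(dir, "layout.tsv"))
  prov <- unclass(ds$config)
  prov$package_version <- as.character(utils::packageVersion("toposcreen"))
  prov$planted <- ds$planted
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a screen dataset from a directory
#'
#' @param dir Directory written by [write_screen_dataset()].
#' @return A `screen_dataset` (config restored from provenance).
#' @export
read_screen_dataset <- function(dir) {
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  config <- do.call(synth_config, prov[setdiff(
    names(prov),
    c("package_version", "planted", "seeding_density_cells_per_cm2"))])
  structure(list(
    cells = read_cells(file.path(dir, "cells.csv")),
    controls = read_controls(file.path(dir, "controls.csv")),
    wells = readr::read_csv(file.path(dir, "wells.csv"),
                            show_col_types = FALSE, progress = FALSE),
    layout = read_layout(file.path(dir, "layout.tsv")),
    planted = tibble::as_tibble(prov$planted),
    config = config),
    class = "screen_dataset")
}
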