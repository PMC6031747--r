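#' Specify one geometric primitive of a topography design
#'
#' Topography patterns are built from three simple geometric elements —
#' circles, triangles, and rectangles — placed inside a square feature cell
#' that is then tiled periodically across the active well area. Sizes and
#' positions are in micrometres; the primitive's bounding circle must stay
#' inside the feature cell so tiling never clips a pillar.
#'
#' @param shape One of `"circle"`, `"triangle"`, `"rectangle"`.
#' @param size_um Characteristic dimension in um: circle diameter, triangle
#'   side (equilateral), or rectangle width.
#' @param offset_um Length-2 numeric, centre position within the feature cell.
#' @param rotation_deg Rotation about the centre, degrees.
#' @param aspect Height/width ratio for rectangles (ignored otherwise).
#' @return A `primitive_spec` list.
#' @export
#' @examples
#' primitive_spec("circle", 10, c(20, 20))
primitive_spec <- function(shape = c("circle", "triangle", "rectangle"),
                           size_um, offset_um, rotation_deg = 0, aspect = 1) {
  shape <- match.arg(shape)
  check_positive_scalar(size_um, "size_um")
  check_positive_scalar(aspect, "aspect")
  if (!is.numeric(offset_um) || length(offset_um) != 2L) {
    abort("`offset_um` must be a length-2 numeric vector.",
          class = "toposcreen_config_error")
  }
  structure(
    list(shape = shape, size_um = size_um, offset_um = as.numeric(offset_um),
         rotation_deg = as.numeric(rotation_deg), aspect = aspect),
    class = "primitive_spec"
  )
}

# radius of the circumscribed circle, used for containment checks
primitive_circumradius <- function(p) {
  switch(p$shape,
    circle    = p$size_um / 2,
    rectangle = p$size_um * sqrt(1 + p$aspect^2) / 2,
    triangle  = p$size_um / sqrt(3)
  )
}

check_primitive_in_cell <- function(p, feature_cell_um) {
  r <- primitive_circumradius(p)
  lo <- p$offset_um - r
  hi <- p$offset_um + r
  if (any(lo < -1e-9) || any(hi > feature_cell_um + 1e-9)) {
    abort("primitive bounding circle extends past the feature cell boundary.",
          class = "toposcreen_config_error")
  }
  invisible(p)
}

#' Generate one topography unit design
#'
#' Draws a seeded random pattern: a number of primitives is sampled uniformly
#' from `n_range`, each with a uniformly chosen shape, size, rotation and a
#' position constrained so the primitive stays inside the feature cell.
#' Overlapping primitives union into compound pillars at rasterization time.
#' Generation is deterministic for a fixed seed.
#'
#' @param seed Integer seed for this unit.
#' @param feature_cell_um Feature-cell (tile) side length, um. Must divide
#'   `well_um`.
#' @param resolution_um Raster resolution, um per raster cell (default 0.5).
#' @param well_um Active well side length, um (default 290: a 300 um pitch
#'   minus a 10 um wall).
#' @param shapes Allowed primitive shapes (non-empty subset of the three).
#' @param n_range Length-2 integer range for the primitive count.
#' @param size_range Length-2 range for primitive sizes, um; sizes are capped
#'   so primitives fit in the feature cell.
#' @param coverage_range Range of the per-unit target foreground coverage
#'   fraction; the primitive count is chosen (within `n_range`) to reach a
#'   coverage drawn uniformly from this range.
#' @param flat If `TRUE`, generate the unpatterned flat control (no
#'   primitives).
#' @param unit_id Identifier string.
#' @return A `topo_unit` object (list with fields `unit_id`, `is_flat`,
#'   `feature_cell_um`, `resolution_um`, `well_um`, `primitives`).
#' @export
#' @examples
#' u <- topo_generate_unit(seed = 1, feature_cell_um = 29)
#' length(u$primitives)
topo_generate_unit <- function(seed, feature_cell_um, resolution_um = 0.5,
                               well_um = 290,
                               shapes = c("circle", "triangle", "rectangle"),
                               n_range = c(1L, 16L), size_range = c(3, 30),
                               coverage_range = c(0.05, 0.65),
                               flat = FALSE, unit_id = "unit") {
  shapes <- match.arg(shapes, several.ok = TRUE)
  if (length(shapes) < 1L) {
    abort("`shapes` must contain at least one allowed shape.",
          class = "toposcreen_config_error")
  }
  if (!divides(well_um, resolution_um)) {
    abort("`resolution_um` must divide the active well side `well_um`.",
          class = "toposcreen_config_error")
  }
  if (!divides(well_um, feature_cell_um)) {
    abort("`feature_cell_um` must divide the active well side `well_um`.",
          class = "toposcreen_config_error")
  }
  if (n_range[1] > n_range[2] || n_range[1] < 1L) {
    abort("`n_range` must be a non-empty positive range.",
          class = "toposcreen_config_error")
  }
  prims <- list()
  if (!flat) {
    w <- feature_cell_um
    prims <- withr::with_seed(seed, {
      # Per-unit size window and a target coverage fraction; the primitive
      # count follows from coverage / mean primitive area so the library
      # spans sparse-to-dense patterns with pillar areas from ~10 to
      # hundreds of um^2 at every feature-cell size.
      s_hi <- runif(1, min(size_range[2], 4), min(size_range[2], 0.6 * w))
      s_lo <- runif(1, min(size_range[1], s_hi), s_hi)
      phi_target <- runif(1, coverage_range[1], coverage_range[2])
      mean_area <- 0.6 * ((s_lo + s_hi) / 2)^2
      k <- max(n_range[1], min(n_range[2],
                               round(phi_target * w^2 / mean_area)))
      lapply(seq_len(k), function(i) {
        shape <- sample(shapes, 1L)
        # cap size so the circumscribed circle fits in the cell
        r_per_size <- switch(shape,
          circle = 0.5, rectangle = sqrt(2) / 2, triangle = 1 / sqrt(3))
        size_max <- min(s_hi, (w / 2) / r_per_size)
        size_min <- min(s_lo, size_max)
        size <- runif(1, size_min, size_max)
        r <- size * r_per_size
        offset <- runif(2, r, w - r)
        primitive_spec(shape, size, offset, rotation_deg = runif(1, 0, 360))
      })
    })
    for (p in prims) check_primitive_in_cell(p, feature_cell_um)
  }
  structure(
    list(unit_id = unit_id, is_flat = flat,
         feature_cell_um = feature_cell_um, resolution_um = resolution_um,
         well_um = well_um, primitives = prims),
    class = "topo_unit"
  )
}

#' @export
print.topo_unit <- function(x, ...) {
  cat(sprintf("<topo_unit %s> %s, feature cell %.3g um, %d primitive(s)\n",
              x$unit_id, if (x$is_flat) "flat" else "patterned",
              x$feature_cell_um, length(x$primitives)))
  invisible(x)
}

# point-in-primitive test for vectors of coordinates (um, cell frame)
point_in_primitive <- function(p, x, y) {
  dx <- x - p$offset_um[1]
  dy <- y - p$offset_um[2]
  th <- -p$rotation_deg * pi / 180
  u <- dx * cos(th) - dy * sin(th)
  v <- dx * sin(th) + dy * cos(th)
  switch(p$shape,
    circle = (dx^2 + dy^2) <= (p$size_um / 2)^2,
    rectangle = (abs(u) <= p$size_um / 2) &
                (abs(v) <= p$size_um * p$aspect / 2),
    triangle = {
      # equilateral triangle, circumradius R, one vertex at angle 90 deg
      R <- p$size_um / sqrt(3)
      ang <- c(90, 210, 330) * pi / 180
      vx <- R * cos(ang); vy <- R * sin(ang)
      inside <- rep(TRUE, length(u))
      for (i in 1:3) {
        j <- if (i == 3) 1L else i + 1L
        ex <- vx[j] - vx[i]; ey <- vy[j] - vy[i]
        # cross product sign: all same side (vertices are counter-clockwise)
        inside <- inside & (ex * (v - vy[i]) - ey * (u - vx[i]) >= 0)
      }
      inside
    }
  )
}

#' Rasterize a topography unit to a binary mask
#'
#' The feature cell is tiled periodically across the active well area;
#' foreground is the union of all primitive rasterizations ("pillar top").
#' The raster convention is row-major with the origin at the well's top-left
#' corner and cell centres at half-resolution offsets.
#'
#' @param design A `topo_unit`.
#' @param resolution_um Raster resolution; defaults to the design's own.
#' @return A logical matrix of size `well_um / resolution_um` squared.
#' @export
topo_mask <- function(design, resolution_um = NULL) {
  stopifnot(inherits(design, "topo_unit"))
  res <- resolution_um %||% design$resolution_um
  if (!divides(design$well_um, res)) {
    abort("`resolution_um` must divide the active well side.",
          class = "toposcreen_config_error")
  }
  n <- as.integer(round(design$well_um / res))
  mask <- matrix(FALSE, n, n)
  if (design$is_flat || length(design$primitives) == 0L) return(mask)
  centers <- (seq_len(n) - 0.5) * res
  w <- design$feature_cell_um
  # coordinates within the repeating feature cell
  u <- centers %% w
  X <- matrix(rep(u, each = n), n, n)       # column coordinate (x)
  Y <- matrix(rep(u, times = n), n, n)      # row coordinate (y)
  for (p in design$primitives) {
    mask <- mask | point_in_primitive(p, X, Y)
  }
  mask
}

#' Generate a catalog of topography unit designs
#'
#' Generates `n_designs` patterned units plus one shared flat control unit.
#' Feature-cell sizes are drawn from tile counts that divide the active well
#' side exactly. Each unit's seed is derived from the master seed and its id,
#' so the catalog is reproducible and insensitive to generation order.
#'
#' @param n_designs Number of unique patterned designs (default 2176).
#' @param master_seed Master seed.
#' @param tiles_per_side Allowed numbers of feature-cell tiles per well side;
#'   the defaults give feature cells of about 10, 21 and 29 um in a 290 um
#'   well.
#' @param flat_id Identifier of the flat control unit.
#' @inheritParams topo_generate_unit
#' @return A tibble with columns `unit_id`, `is_flat`, `feature_cell_um`,
#'   `n_primitives` and a list-column `design` of `topo_unit` objects, with
#'   attribute `catalog_meta`.
#' @export
topo_design_catalog <- function(n_designs = 2176, master_seed = 1,
                                resolution_um = 0.5, well_um = 290,
                                tiles_per_side = c(29L, 14L, 10L),
                                shapes = c("circle", "triangle", "rectangle"),
                                n_range = c(1L, 16L), size_range = c(3, 30),
                                coverage_range = c(0.05, 0.65),
                                flat_id = "FLAT") {
  stopifnot(n_designs >= 1)
  ids <- sprintf("T%04d", seq_len(n_designs))
  designs <- lapply(seq_len(n_designs), function(i) {
    sd_i <- derive_seed(master_seed, paste0("unit:", ids[i]))
    w <- well_um / tiles_per_side[1 + sd_i %% length(tiles_per_side)]
    topo_generate_unit(seed = sd_i, feature_cell_um = w,
                       resolution_um = resolution_um, well_um = well_um,
                       shapes = shapes, n_range = n_range,
                       size_range = size_range,
                       coverage_range = coverage_range, unit_id = ids[i])
  })
  flat <- topo_generate_unit(seed = 0L, feature_cell_um = well_um,
                             resolution_um = resolution_um, well_um = well_um,
                             flat = TRUE, unit_id = flat_id)
  designs <- c(designs, list(flat))
  out <- tibble::tibble(
    unit_id = vapply(designs, `[[`, "", "unit_id"),
    is_flat = vapply(designs, `[[`, NA, "is_flat"),
    feature_cell_um = vapply(designs, `[[`, 0, "feature_cell_um"),
    n_primitives = vapply(designs, function(d) length(d$primitives), 0L),
    design = designs
  )
  attr(out, "catalog_meta") <- list(
    n_designs = n_designs, master_seed = master_seed,
    resolution_um = resolution_um, well_um = well_um, flat_id = flat_id)
  out
}

#' Build the chip layout
#'
#' Places every patterned unit exactly twice and the flat control in exactly
#' four wells, shuffled over the full grid with a fixed seed. The same layout
#' object is shared by all chip replicas of a screen, mirroring fabrication:
#' every chip is embossed from the same mold.
#'
#' @param catalog A design catalog from [topo_design_catalog()], or a
#'   character vector of patterned unit ids.
#' @param seed Placement seed.
#' @param n_rows,n_cols Grid dimensions (default 66 x 66).
#' @param well_pitch_um,well_side_um,wall_width_um Well geometry, um.
#' @param flat_id Flat-control unit id (taken from the catalog when given).
#' @return A tibble with columns `row`, `col` (0-based, row 0 at chip top)
#'   and `unit_id`, of class `chip_layout`, with attribute `layout_meta`.
#' @export
#' @examples
#' cat16 <- topo_design_catalog(n_designs = 16, master_seed = 1)
#' lay <- build_chip_layout(cat16, seed = 1, n_rows = 6, n_cols = 6)
#' nrow(lay)
build_chip_layout <- function(catalog, seed = 1, n_rows = 66, n_cols = 66,
                              well_pitch_um = 300, well_side_um = 300,
                              wall_width_um = 10, flat_id = "FLAT") {
  if (is.data.frame(catalog)) {
    meta <- attr(catalog, "catalog_meta")
    if (!is.null(meta$flat_id)) flat_id <- meta$flat_id
    ids <- catalog$unit_id[!catalog$is_flat]
  } else {
    ids <- as.character(catalog)
  }
  n_wells <- n_rows * n_cols
  if (2L * length(ids) + 4L != n_wells) {
    abort(sprintf(
      "layout arithmetic: 2 x %d patterned + 4 flat wells != %d x %d grid.",
      length(ids), n_rows, n_cols), class = "toposcreen_layout_error")
  }
  wells <- withr::with_seed(seed, sample(c(rep(ids, 2L), rep(flat_id, 4L))))
  out <- tibble::tibble(
    row = rep(seq_len(n_rows) - 1L, each = n_cols),
    col = rep(seq_len(n_cols) - 1L, times = n_rows),
    unit_id = wells
  )
  class(out) <- c("chip_layout", class(out))
  attr(out, "layout_meta") <- list(
    n_rows = n_rows, n_cols = n_cols, n_unique = length(ids),
    n_flat_wells = 4L, well_pitch_um = well_pitch_um,
    well_side_um = well_side_um, wall_width_um = wall_width_um,
    flat_id = flat_id, seed = seed)
  out
}

#' Layout as a unit-id matrix
#'
#' @param layout A `chip_layout`.
#' @return A character matrix of unit ids (rows x cols).
#' @export
layout_grid <- function(layout) {
  meta <- attr(layout, "layout_meta")
  matrix(layout$unit_id, meta$n_rows, meta$n_cols, byrow = TRUE)
}

#' @export
print.chip_layout <- function(x, ...) {
  meta <- attr(x, "layout_meta")
  cat(sprintf(
    "<chip_layout> %d x %d wells, %d unique designs in duplicate, %d flat\n",
    meta$n_rows, meta$n_cols, meta$n_unique, meta$n_flat_wells))
  NextMethod()
}
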