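# Per-design surface descriptors: pillar areas, foreground fraction, and the
# wave-number spectrum of the binary pattern mask.

# Label connected foreground components of a logical matrix.
# `connectivity` 4 is the convention for design-mask pillars, 8 for cell masks.
label_components <- function(mask, connectivity = 4) {
  stopifnot(connectivity %in% c(4, 8))
  n_fg <- sum(mask)
  if (n_fg == 0L) return(list(n = 0L, labels = matrix(0L, nrow(mask), ncol(mask))))
  id <- matrix(0L, nrow(mask), ncol(mask))
  id[mask] <- seq_len(n_fg)
  nr <- nrow(mask); nc <- ncol(mask)
  edges <- list()
  pair_idx <- function(a, b) {
    ok <- a > 0L & b > 0L
    cbind(a[ok], b[ok])
  }
  # horizontal and vertical adjacency
  edges[[1]] <- pair_idx(id[, -nc], id[, -1])
  edges[[2]] <- pair_idx(id[-nr, ], id[-1, ])
  if (connectivity == 8) {
    edges[[3]] <- pair_idx(id[-nr, -nc], id[-1, -1])
    edges[[4]] <- pair_idx(id[-nr, -1], id[-1, -nc])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n_fg, directed = FALSE)
  if (nrow(el) > 0) g <- igraph::add_edges(g, t(el))
  memb <- igraph::components(g)$membership
  lab <- matrix(0L, nr, nc)
  lab[mask] <- as.integer(memb)
  list(n = max(memb), labels = lab)
}

# Radially binned power-spectrum fractions of a binary mask.
# Frequencies are measured as a fraction of the mask's Nyquist frequency;
# the DC component is excluded, and the exhaustive partition (reaching the
# spectral corner at sqrt(2) x Nyquist) sums to one.
wave_number_spectrum <- function(mask, q = c(0.1, 0.25, 0.5)) {
  n <- nrow(mask)
  P <- Mod(stats::fft(mask * 1))^2
  P[1, 1] <- 0 # drop DC
  total <- sum(P)
  k <- seq_len(n) - 1
  f <- ifelse(k <= n / 2, k / n, (k - n) / n) # cycles per raster cell
  R <- sqrt(outer(f^2, f^2, `+`))
  nyq <- 0.5
  wn <- vapply(q, function(qi) sum(P[R <= qi * nyq]) / total, 0)
  edges <- c(0, q, sqrt(2)) * nyq
  part <- vapply(seq_len(length(edges) - 1), function(i) {
    sum(P[R > edges[i] & R <= edges[i + 1]]) / total
  }, 0)
  list(wn = setNames(wn, paste0("wn_", q)),
       partition = setNames(part, paste0("band_", seq_along(part))))
}

# Descriptors from a raw mask; exposed through compute_design_features().
features_from_mask <- function(mask, resolution_um, unit_id = NA_character_,
                               is_flat = NA) {
  active_um2 <- (nrow(mask) * resolution_um) * (ncol(mask) * resolution_um)
  fg <- sum(mask)
  if (fg == 0L) {
    return(tibble::tibble(
      unit_id = unit_id, is_flat = TRUE, n_pillars = 0L,
      pattern_area_um2 = 0, space_area_um2 = 0, foreground_fraction = 0,
      total_foreground_um2 = 0, wn_0.1 = 0, wn_0.25 = 0, wn_0.5 = 0))
  }
  comp <- label_components(mask, connectivity = 4)
  total_fg_um2 <- fg * resolution_um^2
  ws <- wave_number_spectrum(mask)
  tibble::tibble(
    unit_id = unit_id,
    is_flat = isTRUE(is_flat),
    n_pillars = comp$n,
    pattern_area_um2 = total_fg_um2 / comp$n,
    space_area_um2 = (active_um2 - total_fg_um2) / comp$n,
    foreground_fraction = total_fg_um2 / active_um2,
    total_foreground_um2 = total_fg_um2,
    wn_0.1 = ws$wn[["wn_0.1"]],
    wn_0.25 = ws$wn[["wn_0.25"]],
    wn_0.5 = ws$wn[["wn_0.5"]]
  )
}

#' Compute surface-design descriptors for one topography unit
#'
#' Pattern area is the mean area per 4-connected foreground component
#' (pillar); space area is its symmetric counterpart, the background area per
#' pillar. The wave-number descriptors `wn_q` are the fraction of total
#' non-DC spectral power of the binary mask at radial spatial frequencies at
#' most `q` times the Nyquist frequency; `wn_0.1` (the "WN0.1" design
#' parameter) captures both the density of structures and their size: coarse,
#' widely spaced pillars concentrate power at low frequency.
#'
#' @param design A `topo_unit`.
#' @param resolution_um Raster resolution used for the computation; defaults
#'   to the design's own.
#' @return A one-row tibble of descriptors. Flat designs return zeroed
#'   features without error.
#' @export
compute_design_features <- function(design, resolution_um = NULL) {
  stopifnot(inherits(design, "topo_unit"))
  res <- resolution_um %||% design$resolution_um
  mask <- topo_mask(design, res)
  features_from_mask(mask, res, unit_id = design$unit_id,
                     is_flat = design$is_flat)
}

#' Compute design descriptors for a whole catalog
#'
#' @param catalog A catalog tibble from [topo_design_catalog()].
#' @param resolution_um Raster resolution for feature computation. The
#'   default, 1 um, keeps catalog-scale computation light; per-design area
#'   accuracy at this resolution is well within the tolerances used
#'   downstream.
#' @param progress Show a progress message every 500 designs.
#' @return A tibble with one row per unit.
#' @export
design_features <- function(catalog, resolution_um = 1, progress = FALSE) {
  stopifnot(is.data.frame(catalog), "design" %in% names(catalog))
  n <- nrow(catalog)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- compute_design_features(catalog$design[[i]], resolution_um)
    if (progress && i %% 500 == 0) inform(sprintf("features: %d/%d", i, n))
  }
  dplyr::bind_rows(out)
}

#' Classify a design into a plantable archetype
#'
#' Labels designs by the pillar-geometry regimes associated with high and low
#' marker induction: `high_like` surfaces have pillars with area between
#' `area_range[1]` and `area_range[2]` um^2 and moderate spacing (foreground
#' fraction at most `sparse_cutoff`); `low_like` surfaces have densely packed
#' pillars (foreground fraction at least `dense_cutoff`) with area below
#' `area_range[1]` um^2. Used by the synthetic screen generator to plant
#' plausible hit surfaces; flat designs are always `other`.
#'
#' @param features A design-features tibble from [design_features()].
#' @param area_range Pillar-area window for `high_like`, um^2.
#' @param dense_cutoff Foreground fraction at or above which a pattern counts
#'   as dense.
#' @param sparse_cutoff Foreground fraction above which spacing is no longer
#'   "moderate".
#' @return The input tibble with an added factor column `archetype`.
#' @export
classify_design_archetype <- function(features, area_range = c(100, 400),
                                      dense_cutoff = 0.15,
                                      sparse_cutoff = 0.30) {
  check_columns(features,
                c("pattern_area_um2", "foreground_fraction", "is_flat"),
                "design features")
  a <- features$pattern_area_um2
  phi <- features$foreground_fraction
  arch <- ifelse(
    !features$is_flat & a >= area_range[1] & a <= area_range[2] &
      phi <= sparse_cutoff, "high_like",
    ifelse(!features$is_flat & a > 0 & a < area_range[1] & phi >= dense_cutoff,
           "low_like", "other"))
  dplyr::mutate(features,
                archetype = factor(arch, c("high_like", "low_like", "other")))
}
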