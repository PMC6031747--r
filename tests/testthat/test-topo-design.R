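# Design generation, rasterization, layout arithmetic and descriptors.

test_that("flat control units rasterize to an all-background mask", {
  flat <- topo_generate_unit(seed = 1, feature_cell_um = 29, flat = TRUE)
  expect_true(flat$is_flat)
  expect_length(flat$primitives, 0)
  m <- topo_mask(flat)
  expect_equal(dim(m), c(580, 580))
  expect_false(any(m))
})

test_that("rasterized primitive areas match closed forms", {
  base <- list(unit_id = "x", is_flat = FALSE, feature_cell_um = 58,
               resolution_um = 1, well_um = 290)
  # axis-aligned 10x10 um rectangle, 5x5 tiling: exactly 2500 um^2 foreground
  rect <- structure(modifyList(base, list(
    primitives = list(primitive_spec("rectangle", 10, c(29, 29))))),
    class = "topo_unit")
  expect_equal(sum(topo_mask(rect, 1)) * 1^2, 2500)

  # circle of diameter 10: per-tile area within 5% of pi * 25 at 0.5 um
  circ <- structure(modifyList(base, list(
    primitives = list(primitive_spec("circle", 10, c(29, 29))))),
    class = "topo_unit")
  per_tile <- sum(topo_mask(circ, 0.5)) * 0.5^2 / 25
  expect_lt(abs(per_tile - pi * 25) / (pi * 25), 0.05)

  # equilateral triangle side 12, rotated: area sqrt(3)/4 * 144 within 5%
  tri <- structure(modifyList(base, list(
    primitives = list(primitive_spec("triangle", 12, c(29, 29),
                                     rotation_deg = 25)))),
    class = "topo_unit")
  per_tile <- sum(topo_mask(tri, 0.25)) * 0.25^2 / 25
  expect_lt(abs(per_tile - sqrt(3) / 4 * 144) / (sqrt(3) / 4 * 144), 0.05)
})

test_that("rasterization error does not grow when the resolution is halved", {
  base <- list(unit_id = "x", is_flat = FALSE, feature_cell_um = 58,
               resolution_um = 1, well_um = 290)
  shapes <- list(
    list(p = primitive_spec("circle", 11, c(29, 29)), a = pi * 5.5^2),
    list(p = primitive_spec("rectangle", 9, c(29, 29), rotation_deg = 30),
         a = 81),
    list(p = primitive_spec("triangle", 13, c(29, 29), rotation_deg = 10),
         a = sqrt(3) / 4 * 169))
  for (s in shapes) {
    d <- structure(modifyList(base, list(primitives = list(s$p))),
                   class = "topo_unit")
    errs <- vapply(c(2, 1, 0.5, 0.25), function(res) {
      abs(sum(topo_mask(d, res)) * res^2 / 25 - s$a) / s$a
    }, 0)
    # error shrinks with resolution; fluctuation below half a percent is
    # rasterization noise, not divergence
    expect_true(all(diff(errs) <= 0.005))
    expect_lt(errs[length(errs)], 0.03)
  }
})

test_that("unit generation is deterministic and respects the feature cell", {
  u1 <- topo_generate_unit(seed = 42, feature_cell_um = 29)
  u2 <- topo_generate_unit(seed = 42, feature_cell_um = 29)
  expect_identical(u1, u2)
  for (p in u1$primitives) {
    r <- toposcreen:::primitive_circumradius(p)
    expect_true(all(p$offset_um - r >= -1e-9))
    expect_true(all(p$offset_um + r <= 29 + 1e-9))
  }
  expect_error(topo_generate_unit(seed = 1, feature_cell_um = 29,
                                  resolution_um = 0.7),
               class = "toposcreen_config_error")
  expect_error(topo_generate_unit(seed = 1, feature_cell_um = 29,
                                  shapes = character(0)))
})

test_that("chip layout satisfies the multiplicity invariants", {
  lay <- ts_layout6()
  expect_equal(nrow(lay), 36)
  counts <- table(lay$unit_id)
  meta <- attr(lay, "layout_meta")
  expect_equal(unname(counts[[meta$flat_id]]), 4)
  expect_true(all(counts[names(counts) != meta$flat_id] == 2))
  expect_equal(meta$n_unique, 16)
  # determinism: same seed gives a bit-identical grid
  lay2 <- build_chip_layout(ts_catalog16(), seed = 2, n_rows = 6, n_cols = 6)
  expect_identical(layout_grid(lay), layout_grid(lay2))
  # arithmetic mismatch errors
  expect_error(build_chip_layout(ts_catalog16(), seed = 1,
                                 n_rows = 6, n_cols = 7),
               class = "toposcreen_layout_error")
})

test_that("layout conservation holds across grid sizes", {
  for (n_side in c(6, 10)) {
    n_unique <- (n_side^2 - 4) / 2
    cat_n <- topo_design_catalog(n_designs = n_unique, master_seed = 5)
    lay <- build_chip_layout(cat_n, seed = 5, n_rows = n_side,
                             n_cols = n_side)
    counts <- table(lay$unit_id)
    expect_equal(sum(counts), n_side^2)
    expect_true(all(counts[names(counts) != "FLAT"] == 2))
  }
})

test_that("design features match direct counting on a known tiling", {
  # 10x10 um squares in a 58 um cell, 290 um well: 25 pillars of 100 um^2
  d <- structure(list(unit_id = "x", is_flat = FALSE, feature_cell_um = 58,
                      resolution_um = 1, well_um = 290,
                      primitives = list(primitive_spec("rectangle", 10,
                                                       c(29, 29)))),
                 class = "topo_unit")
  f <- compute_design_features(d)
  expect_equal(f$n_pillars, 25)
  expect_equal(f$pattern_area_um2, 100)
  expect_equal(f$foreground_fraction, 2500 / 84100)
  expect_equal(f$space_area_um2, (84100 - 2500) / 25)
  # flat design: zeroed features, no error
  flat <- topo_generate_unit(seed = 1, feature_cell_um = 29, flat = TRUE)
  ff <- compute_design_features(flat)
  expect_equal(ff$pattern_area_um2, 0)
  expect_equal(ff$n_pillars, 0L)
  expect_equal(ff$foreground_fraction, 0)
})

test_that("wave-number partition is exhaustive and tracks structure size", {
  # partition sums to one for any non-flat mask
  for (i in 1:5) {
    u <- topo_generate_unit(seed = 100 + i, feature_cell_um = 29,
                            resolution_um = 1)
    ws <- toposcreen:::wave_number_spectrum(topo_mask(u))
    expect_equal(sum(ws$partition), 1, tolerance = 1e-9)
    expect_true(all(ws$wn >= 0 & ws$wn <= 1))
  }
  # same foreground fraction, coarser pillars: WN0.1 strictly larger
  mk <- function(cell, side) {
    structure(list(unit_id = "x", is_flat = FALSE, feature_cell_um = cell,
                   resolution_um = 1, well_um = 280,
                   primitives = list(primitive_spec("rectangle", side,
                                                    c(cell / 2, cell / 2)))),
              class = "topo_unit")
  }
  fine <- compute_design_features(mk(20, 10))   # 10 um pillars, phi = 0.25
  coarse <- compute_design_features(mk(40, 20)) # 20 um pillars, phi = 0.25
  expect_equal(fine$foreground_fraction, coarse$foreground_fraction)
  expect_gt(coarse$wn_0.1, fine$wn_0.1)
})

test_that("design features are invariant to shifting the tiling origin", {
  u <- topo_generate_unit(seed = 9, feature_cell_um = 29, resolution_um = 1)
  m <- topo_mask(u, 1)
  shift <- 29 # one full feature cell in raster cells at 1 um
  m_shift <- m[c((shift + 1):nrow(m), 1:shift), c((shift + 1):ncol(m), 1:shift)]
  f1 <- toposcreen:::features_from_mask(m, 1)
  f2 <- toposcreen:::features_from_mask(m_shift, 1)
  expect_equal(f1$n_pillars, f2$n_pillars)
  expect_equal(f1$pattern_area_um2, f2$pattern_area_um2)
  expect_equal(f1$wn_0.1, f2$wn_0.1, tolerance = 1e-9)
})

test_that("archetype classification follows the pillar-area and density rules", {
  f <- tibble::tibble(
    unit_id = c("a", "b", "c"),
    is_flat = c(FALSE, FALSE, TRUE),
    pattern_area_um2 = c(250, 60, 0),
    foreground_fraction = c(0.10, 0.20, 0))
  out <- classify_design_archetype(f)
  expect_equal(as.character(out$archetype), c("high_like", "low_like", "other"))
})
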