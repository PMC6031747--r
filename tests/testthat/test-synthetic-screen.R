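# Generator reproducibility, conservation, calibration and round-trips.

test_that("simulation is reproducible and conserves cells", {
  ds <- ts_small_screen()
  ds2 <- simulate_screen(ds$config, ts_layout6(), ts_features16())
  expect_identical(ds$cells, ds2$cells)
  expect_identical(ds$controls, ds2$controls)
  # conservation: per-well counts sum to the number of cell records
  expect_equal(sum(ds$wells$n_cells), nrow(ds$cells))
  expect_true(all(ds$cells$true_class %in% c("pos", "neg")))
  # every cell's well maps to a layout unit
  expect_true(all(ds$cells$unit_id %in% ts_layout6()$unit_id))
  # replica structure: each unique surface occupies n_chips x 2 wells
  reps <- ds$wells |>
    dplyr::filter(unit_id != "FLAT") |>
    dplyr::count(unit_id)
  expect_true(all(reps$n == ds$config$n_chips * 2))
})

test_that("planted effects shift positive fractions monotonically", {
  fa <- classify_design_archetype(ts_features16())
  ids <- head(fa$unit_id[!fa$is_flat], 2)
  base_cfg <- function(eff) synth_config(
    planted_high_ids = ids, planted_low_ids = character(0),
    effect_high = eff, cells_per_well_mean = 40, n_chips = 4,
    master_seed = 77)
  frac_planted <- function(eff) {
    ds <- simulate_screen(base_cfg(eff), ts_layout6())
    mean(ds$cells$true_class[ds$cells$unit_id %in% ids] == "pos")
  }
  f1 <- frac_planted(0.10)
  f2 <- frac_planted(0.20)
  expect_gt(f2, f1)
  # null screen: no planted surfaces, class rate near baseline everywhere
  null_cfg <- synth_config(n_planted_high = 0, n_planted_low = 0,
                           cells_per_well_mean = 40, master_seed = 5)
  ds0 <- simulate_screen(null_cfg, ts_layout6())
  expect_equal(nrow(ds0$planted), 0)
  expect_lt(abs(mean(ds0$cells$true_class == "pos") - 0.07), 0.01)
})

test_that("configuration errors are caught", {
  expect_error(synth_config(baseline_positive_weight = 1.5),
               class = "toposcreen_config_error")
  expect_error(synth_config(planted_high_ids = "T0001",
                            planted_low_ids = "T0001"),
               class = "toposcreen_config_error")
  cfg <- synth_config(planted_high_ids = "NOPE",
                      planted_low_ids = character(0), master_seed = 1)
  expect_error(simulate_screen(cfg, ts_layout6()),
               class = "toposcreen_config_error")
  expect_error(simulate_controls(synth_config(), n_cells = 50),
               class = "toposcreen_config_error")
})

test_that("pure-component negative control matches the lognormal quantile", {
  # with a zero positive weight the negative control is a single lognormal;
  # its 93rd percentile has the closed form exp(meanlog + z_0.93 * sdlog)
  cfg <- synth_config(baseline_positive_weight = 0,
                      pos_control_positive_weight = 1, master_seed = 31)
  ctl <- simulate_controls(cfg, n_cells = 2000)
  neg <- ctl$icam1_median_intensity[ctl$condition == "neg"]
  pos <- ctl$icam1_median_intensity[ctl$condition == "pos"]
  expected <- exp(4.0 + qnorm(0.93) * 0.4) # ~98.8 a.u.
  expect_equal(quantile(neg, 0.93, names = FALSE), expected,
               tolerance = 0.05)
  expect_gt(mean(pos), mean(neg))
  # degenerate mixture: log-samples are plain Gaussians at the component means
  expect_equal(mean(log(neg)), 4.0, tolerance = 0.05)
  expect_equal(mean(log(pos)), 5.18, tolerance = 0.05)
})

test_that("chip batch factor controls between-chip intensity spread", {
  fa <- ts_features16()
  cfg0 <- synth_config(n_planted_high = 0, n_planted_low = 0,
                       chip_scale_sd = 0, cells_per_well_mean = 40,
                       master_seed = 13)
  ds0 <- simulate_screen(cfg0, ts_layout6())
  med0 <- tapply(ds0$cells$icam1_median_intensity, ds0$cells$chip_id, median)
  expect_lt(diff(range(log(med0))), 0.1)
  cfg1 <- synth_config(n_planted_high = 0, n_planted_low = 0,
                       chip_scale_sd = 0.15, cells_per_well_mean = 40,
                       master_seed = 13)
  ds1 <- simulate_screen(cfg1, ts_layout6())
  med1 <- tapply(ds1$cells$icam1_median_intensity, ds1$cells$chip_id, median)
  expect_gt(sd(log(med1)), sd(log(med0)))
})

test_that("datasets round-trip losslessly and reproduce from provenance", {
  ds <- ts_small_screen()
  dir <- withr::local_tempdir()
  write_screen_dataset(ds, dir)
  back <- read_screen_dataset(dir)
  expect_equal(as.data.frame(back$cells), as.data.frame(ds$cells))
  expect_equal(as.data.frame(back$controls), as.data.frame(ds$controls))
  expect_identical(layout_grid(back$layout), layout_grid(ds$layout))
  # zero-cell wells stay present in the well index
  expect_true(any(back$wells$n_cells == 0) || all(back$wells$n_cells > 0))
  expect_equal(nrow(back$wells), ds$config$n_chips * nrow(ds$layout))
  # provenance reproduces the tables bit-identically
  ds2 <- simulate_screen(back$config, back$layout)
  expect_equal(as.data.frame(ds2$cells), as.data.frame(ds$cells))
})
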