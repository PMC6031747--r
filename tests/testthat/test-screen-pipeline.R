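# QC, threshold calibration/application, hit calling and summaries.

test_that("QC excludes exactly the cells outside median +/- 1.5 IQR", {
  # identical cells: IQR = 0, bounds collapse to the median, all retained
  same <- tibble::tibble(unit_id = "u", cell_id = as.character(1:10),
                         area_um2 = 100, perimeter_um = 40)
  expect_equal(qc_filter(same)$n_excluded, 0)

  # 15 cells near 100 plus one at 1000: only the outlier is excluded
  areas <- c(96, 97, 97, 98, 99, 99, 100, 100, 100, 101, 101, 102, 103,
             104, 104, 1000)
  cells <- tibble::tibble(unit_id = "u", cell_id = as.character(1:16),
                          area_um2 = areas, perimeter_um = 40)
  med <- median(areas); iqr <- IQR(areas)
  expect_true(1000 > med + 1.5 * iqr) # hand check of the oracle bound
  qc <- qc_filter(cells)
  expect_equal(qc$n_excluded, 1)
  expect_false(qc$flags$qc_pass[16])

  # a cell exactly on the bound is retained (strict inequality excludes)
  bnd <- qc_filter(cells)$bounds
  at_bound <- tibble::tibble(unit_id = "u", cell_id = "x",
                             area_um2 = bnd$area_hi, perimeter_um = 40)
  qc2 <- qc_filter(dplyr::bind_rows(cells[-16, ], at_bound))
  expect_true(all(qc2$flags$qc_pass))
})

test_that("QC flags small groups and rejects missing features", {
  few <- tibble::tibble(unit_id = "u", cell_id = as.character(1:3),
                        area_um2 = c(1, 100, 10000), perimeter_um = 40)
  qc <- qc_filter(few)
  expect_equal(qc$n_excluded, 0)
  expect_true(qc$bounds$small_group[1])
  bad <- tibble::tibble(unit_id = "u", cell_id = c("a", "b", "c", "d", "e"),
                        area_um2 = c(1, 2, NA, 4, 5), perimeter_um = 40)
  expect_error(qc_filter(bad), "cell `c`", class = "toposcreen_schema_error")
})

test_that("QC is a monotone filter (idempotent on its own output)", {
  ds <- ts_small_screen()
  qc1 <- qc_filter(ds$cells)
  qc2 <- qc_filter(qc1$cells)
  expect_lte(qc2$n_excluded, qc1$n_excluded)
})

test_that("calibration finds the equal-variance crossing and its percentile", {
  set.seed(88)
  neg <- rlnorm(5000, 4.0, 0.4)
  pos <- rlnorm(5000, 5.18, 0.4)
  cal <- calibrate_threshold(neg, pos)
  # equal-variance components cross at exp((m1 + m2) / 2)
  expect_equal(log(cal$threshold), (4.0 + 5.18) / 2, tolerance = 0.02)
  expect_equal(cal$calibration_percentile, 93, tolerance = 2)

  # far-separated positive control pushes the percentile towards 100
  pos_far <- rlnorm(5000, 6.5, 0.4)
  expect_warning(cal_far <- calibrate_threshold(neg, pos_far), "> 99")
  expect_gt(cal_far$calibration_percentile, 99)

  # disjoint supports and identical samples are errors
  expect_error(calibrate_threshold(neg, neg + max(neg) * 10),
               class = "toposcreen_calibration_error")
  expect_error(calibrate_threshold(neg, neg),
               class = "toposcreen_calibration_error")
  expect_error(calibrate_threshold(neg[1:50], pos[1:50]),
               class = "toposcreen_config_error")
})

test_that("per-chip thresholding flags the complementary percentile", {
  # chip with intensities 1..100: type-7 93rd percentile cutoff lies
  # between the 93rd and 94th order statistics; exactly 7 cells exceed it
  cells <- tibble::tibble(chip_id = "c1", cell_id = as.character(1:100),
                          icam1_median_intensity = sample(1:100))
  out <- apply_threshold(cells, 93)
  thr <- chip_thresholds(out)
  expect_gt(thr$threshold, 93); expect_lt(thr$threshold, 94)
  expect_equal(sum(out$icam1_positive), 7)
  expect_setequal(cells$icam1_median_intensity[out$icam1_positive], 94:100)

  # percentile flags are invariant to per-chip rescaling
  sc <- cells; sc$icam1_median_intensity <- sc$icam1_median_intensity * 37.5
  expect_identical(apply_threshold(sc, 93)$icam1_positive,
                   out$icam1_positive)

  # two chips with shifted distributions each flag ~7%
  set.seed(3)
  two <- tibble::tibble(
    chip_id = rep(c("a", "b"), each = 4000),
    cell_id = as.character(1:8000),
    icam1_median_intensity = c(rlnorm(4000, 4, 0.4),
                               3 * rlnorm(4000, 4, 0.4)))
  fr <- tapply(apply_threshold(two, 93)$icam1_positive, two$chip_id, mean)
  expect_equal(as.numeric(fr), c(0.07, 0.07), tolerance = 0.001)

  expect_error(apply_threshold(cells[1:30, ], 93),
               class = "toposcreen_config_error")
})

test_that("the flagged fraction matches 1 - p/100 within 1/n on simulations", {
  for (seed in c(1, 2)) {
    cfg <- synth_config(n_planted_high = 0, n_planted_low = 0,
                        cells_per_well_mean = 40, n_chips = 3,
                        master_seed = seed)
    ds <- simulate_screen(cfg, ts_layout6())
    fl <- apply_threshold(ds$cells, 93)
    frac <- tapply(fl$icam1_positive, fl$chip_id, mean)
    n_chip <- table(fl$chip_id)
    expect_true(all(abs(frac - 0.07) <= 1 / as.numeric(n_chip) + 1e-9))
  }
})

test_that("the chi-square statistic matches the expected-count oracle", {
  # hand example: surface (40 pos, 120 neg) vs reference (22 pos, 298 neg)
  t1 <- toposcreen:::test_2x2(40, 120, 22, 298)
  expect_equal(t1$stat, oracle_chi2(40, 120, 22, 298), tolerance = 1e-9)
  expect_identical(t1$method, "chisq")
  # equal tables give a zero statistic and p = 1
  t0 <- toposcreen:::test_2x2(22, 298, 22, 298)
  expect_equal(t0$stat, 0)
  expect_equal(t0$p, 1)
  # cross-check against the standard implementation, no continuity correction
  ct <- suppressWarnings(chisq.test(matrix(c(40, 22, 120, 298), 2),
                                    correct = FALSE))
  expect_equal(t1$stat, unname(ct$statistic), tolerance = 1e-9)
  expect_equal(t1$p, ct$p.value, tolerance = 1e-9)
})

test_that("Fisher fallback triggers exactly when an expected count is < 5", {
  set.seed(12)
  for (i in 1:200) {
    a <- rpois(1, 6); b <- rpois(1, 40); c <- rpois(1, 12); d <- rpois(1, 60)
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    n <- a + b + c + d
    expd <- c((a + b) * (a + c), (a + b) * (b + d),
              (c + d) * (a + c), (c + d) * (b + d)) / n
    res <- toposcreen:::test_2x2(a, b, c, d)
    if (any(expd < 5)) {
      expect_identical(res$method, "fisher")
      expect_equal(res$p, fisher.test(matrix(c(a, c, b, d), 2))$p.value)
    } else {
      expect_identical(res$method, "chisq")
      expect_equal(res$stat, oracle_chi2(a, b, c, d), tolerance = 1e-9)
    }
  }
})

test_that("hit calling classifies, ranks and flags zero-cell surfaces", {
  ds <- ts_small_screen()
  qc <- qc_filter(ds$cells)
  fl <- apply_threshold(qc$cells, 93)
  hits <- call_hits(fl, ts_layout6())
  expect_s3_class(hits, "topo_hit_table")
  expect_equal(sort(hits$rank), seq_len(nrow(hits)))
  expect_equal(nrow(hits), 16)
  expect_true(all(hits$n_pos <= hits$n_cells))
  meta <- attr(hits, "hit_meta")
  # classes respect direction and significance
  high <- hits[hits$class == "High", ]
  expect_true(all(high$pos_fraction > meta$ref_fraction))
  expect_true(all(high$p_value < 0.05))
  low <- hits[hits$class == "Low", ]
  expect_true(all(low$pos_fraction < meta$ref_fraction))
  # table is sorted by decreasing positive fraction
  expect_true(all(diff(hits$pos_fraction) <= 1e-12))

  # a zero-cell surface is NS with p = 1 and ranks last
  fl_drop <- fl[fl$unit_id != hits$unit_id[1], ]
  hits2 <- call_hits(fl_drop, ts_layout6())
  row <- hits2[hits2$unit_id == hits$unit_id[1], ]
  expect_equal(row$n_cells, 0L)
  expect_equal(row$p_value, 1)
  expect_equal(as.character(row$class), "NS")
  expect_equal(row$rank, nrow(hits2))
})

test_that("screen summary recovers the generator's structure", {
  ds <- ts_small_screen()
  qc <- qc_filter(ds$cells)
  fl <- apply_threshold(qc$cells, 93)
  hits <- call_hits(fl, ts_layout6())
  summ <- summarize_screen(fl, hits, ts_layout6())
  expect_equal(nrow(summ$per_chip), ds$config$n_chips)
  expect_equal(nrow(summ$per_surface), 16)
  # actin correlation on the log scale recovers the configured rho = 0.5
  expect_equal(summ$actin_icam1_log_pearson, 0.5, tolerance = 0.05)
  # flat-only subset compared with itself: rank-sum p ~ 1
  flat_cells <- fl[fl$unit_id == "FLAT", ]
  wt <- wilcox.test(flat_cells$icam1_median_intensity,
                    flat_cells$icam1_median_intensity)
  expect_gt(wt$p.value, 0.99)
})
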