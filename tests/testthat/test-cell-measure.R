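# Shape and intensity measurement against closed forms and brute force.

test_that("disk features match their closed forms", {
  m <- make_disk(40)
  f <- measure_shape(m)
  expect_equal(f$form_factor, 1, tolerance = 0.05)
  expect_gte(f$solidity, 0.98)
  expect_lte(f$eccentricity, 0.05)
  # median depth of a disk: area at depth >= d is pi (r - d)^2, half at
  # d = (1 - 1/sqrt(2)) r
  expect_equal(f$median_radius_um, (1 - 1 / sqrt(2)) * 40, tolerance = 0.05)
})

test_that("square and ellipse features match their closed forms", {
  f <- measure_shape(make_square(50))
  expect_lt(abs(f$form_factor - pi / 4), 0.05)
  expect_gte(f$solidity, 0.99)
  expect_lt(f$eccentricity, 0.05)
  # 8:1 ellipse: e = sqrt(1 - 1/64)
  f8 <- measure_shape(make_ellipse(32, 4, angle_deg = 20, n = 75))
  expect_lt(abs(f8$eccentricity - sqrt(1 - 1 / 64)), 0.01)
})

test_that("distance transform equals all-pairs brute force on random masks", {
  set.seed(404)
  for (i in 1:6) {
    m <- matrix(runif(64 * 64) < runif(1, 0.3, 0.7), 64, 64)
    expect_equal(toposcreen:::distance_transform(m), oracle_distance(m),
                 tolerance = 1e-12)
  }
})

test_that("eccentricity agrees with brute-force enumeration", {
  set.seed(405)
  shapes <- list(make_disk(10), make_ellipse(20, 6, 35),
                 generate_cell_fixture("multilobed", 48, 2)$mask)
  for (m in shapes) {
    expect_equal(toposcreen:::eccentricity_from_moments(m),
                 oracle_eccentricity(m), tolerance = 1e-9)
  }
})

test_that("shape features are rotation invariant within discretization", {
  e0 <- measure_shape(make_ellipse(24, 8, 0, n = 60))
  e90 <- measure_shape(make_ellipse(24, 8, 90, n = 60))
  e37 <- measure_shape(make_ellipse(24, 8, 37, n = 60))
  for (col in c("area_um2", "perimeter_um", "form_factor", "solidity")) {
    expect_equal(e90[[col]], e0[[col]], tolerance = 0.05)
    expect_equal(e37[[col]], e0[[col]], tolerance = 0.06)
  }
  # the median radius of thin shapes is quantised in ~0.4 px distance
  # levels, so rotation moves it slightly more
  expect_equal(e90$median_radius_um, e0$median_radius_um, tolerance = 0.05)
  expect_equal(e37$median_radius_um, e0$median_radius_um, tolerance = 0.10)
  expect_equal(e37$eccentricity, e0$eccentricity, tolerance = 0.02)
})

test_that("integer upscaling obeys the scale laws", {
  # axis-aligned square: the chain-code perimeter scales almost exactly
  sq <- make_square(30)
  a_sq <- measure_shape(sq)
  b_sq <- measure_shape(upscale_mask(sq, 2L))
  expect_equal(b_sq$area_um2 / a_sq$area_um2, 4)
  expect_equal(b_sq$perimeter_um / a_sq$perimeter_um, 2, tolerance = 0.03)
  # the median of the integer-valued depth map quantises the ratio
  expect_equal(b_sq$median_radius_um / a_sq$median_radius_um, 2,
               tolerance = 0.10)
  # disk: block upscaling introduces the staircase bias of chain-code
  # estimators (documented); area is exact, the rest approximate
  m <- make_disk(15)
  a <- measure_shape(m)
  for (s in c(2L, 3L)) {
    b <- measure_shape(upscale_mask(m, s))
    expect_equal(b$area_um2 / a$area_um2, s^2)
    expect_equal(b$perimeter_um / a$perimeter_um, s, tolerance = 0.20)
    expect_equal(b$solidity, a$solidity, tolerance = 0.05)
    expect_equal(b$median_radius_um / a$median_radius_um, s,
                 tolerance = 0.12)
    expect_lt(abs(b$eccentricity - a$eccentricity), 0.05)
  }
})

test_that("degenerate and invalid masks are handled as specified", {
  expect_error(measure_shape(matrix(FALSE, 4, 4)),
               class = "toposcreen_measure_error")
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  f <- measure_shape(one, pixel_size_um = 2)
  expect_true(f$degenerate)
  expect_equal(f$area_um2, 4)          # pixel^2
  expect_equal(f$median_radius_um, 1)  # half a pixel
  two <- one; two[1, 1] <- TRUE        # two 8-components
  expect_error(measure_shape(two), class = "toposcreen_measure_error")
})

test_that("intensity statistics follow the stated conventions", {
  m <- make_square(4, pad = 2) # 16 pixels
  img <- matrix(7, nrow(m), ncol(m))
  r <- measure_intensity(m, img)
  expect_equal(r$median_intensity, 7)
  expect_equal(r$integrated_intensity, 7 * 16)
  # scale equivariance
  r2 <- measure_intensity(m, 2 * img)
  expect_equal(r2$median_intensity, 14)
  # checkerboard over an even-count mask: median is the central-pair mean
  cb <- outer(seq_len(nrow(m)), seq_len(ncol(m)),
              function(i, j) ifelse((i + j) %% 2 == 0, 0, 10))
  expect_equal(measure_intensity(m, cb)$median_intensity, 5)
  # background pixels never contribute
  img_bg <- img; img_bg[!m] <- 1e6
  expect_equal(measure_intensity(m, img_bg)$median_intensity, 7)
  expect_error(measure_intensity(matrix(TRUE, 10, 10), matrix(0, 5, 5)),
               class = "toposcreen_measure_error")
})

test_that("cell fixtures express their archetype and are seed-stable", {
  f1 <- generate_cell_fixture("round", 64, 7)
  f2 <- generate_cell_fixture("round", 64, 7)
  expect_identical(f1$mask, f2$mask)
  expect_identical(f1$image, f2$image)
  r <- measure_shape(generate_cell_fixture("round", 64, 1)$mask)
  s <- measure_shape(generate_cell_fixture("spindle", 64, 1)$mask)
  ml <- measure_shape(generate_cell_fixture("multilobed", 64, 1)$mask)
  expect_lt(r$eccentricity, 0.3)
  expect_gt(s$eccentricity, 0.95)
  expect_lt(ml$solidity, 0.8)
  expect_gt(s$eccentricity, r$eccentricity)
  expect_lt(ml$solidity, r$solidity)
})

test_that("measure_cells handles labelled images end to end", {
  lab <- matrix(0L, 40, 80)
  lab[5:20, 5:20][make_disk(7, 16)] <- 1L
  lab[6:35, 40:69][make_ellipse(14, 5, 15, n = 30)] <- 2L
  img <- matrix(100, 40, 80)
  out <- measure_cells(lab, img, pixel_size_um = 0.5)
  expect_equal(out$label, c(1L, 2L))
  expect_equal(out$median_intensity, c(100, 100))
  expect_gt(out$eccentricity[2], out$eccentricity[1])
  expect_equal(out$area_um2[1], sum(lab == 1) * 0.25)
})
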