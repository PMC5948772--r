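test_that("reflectance calibration satisfies its defining identities", {
  d <- c(3, 4, 5)
  dark <- array(10, d); white <- array(90, d)

  expect_equal(as.vector(calibrate_reflectance(white, dark, white)),
               rep(1, prod(d)))
  expect_equal(as.vector(calibrate_reflectance(dark, dark, white)),
               rep(0, prod(d)))
  expect_equal(calibrate_reflectance(array(50, d), dark, white)[1, 1, 1],
               0.5)

  # scale invariance: common positive factor cancels
  raw <- array(runif(prod(d), 20, 80), d)
  R1 <- calibrate_reflectance(raw, dark, white)
  R2 <- calibrate_reflectance(7.3 * raw, 7.3 * dark, 7.3 * white)
  expect_equal(as.vector(R1), as.vector(R2), tolerance = 1e-12)
})

test_that("white == dark anywhere is a hard, located error", {
  d <- c(2, 3, 4)
  dark <- array(10, d); white <- array(90, d)
  white[2, 3, 1] <- 10
  expect_error(calibrate_reflectance(array(50, d), dark, white),
               "line 2, pixel 3, band 1")
})

test_that("single-line references broadcast along the scan axis", {
  d <- c(4, 3, 5)
  raw <- array(rnorm(prod(d), 50, 5), d)
  dark_line <- matrix(10, d[2], d[3])
  white_line <- matrix(90, d[2], d[3])
  R_line <- calibrate_reflectance(raw, dark_line, white_line)
  R_full <- calibrate_reflectance(raw, array(10, d), array(90, d))
  expect_equal(as.vector(R_line), as.vector(R_full))
})

test_that("ROI extraction averages exactly the masked pixels", {
  cube <- array(0, c(2, 2, 3))
  cube[1, 1, ] <- c(0.2, 0.5, 0.9)
  cube[1, 2, ] <- 0.4; cube[2, 1, ] <- 0.6; cube[2, 2, ] <- 0.8
  grid <- wavelength_grid(c(1000, 1100, 1200))

  # single-pixel mask returns that pixel's spectrum
  roi <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  sm <- extract_roi_spectra(cube, roi, "RD-U", grid)
  expect_equal(unname(sm$reflectance[1, ]), c(0.2, 0.5, 0.9))

  # 4-pixel mask averages
  roi4 <- matrix(1L, 2, 2)
  cube2 <- array(rep(c(0.2, 0.4, 0.6, 0.8), 3), c(2, 2, 3))
  sm4 <- extract_roi_spectra(cube2, roi4, "RD-U", grid)
  expect_equal(unname(sm4$reflectance[1, ]), rep(0.5, 3))

  # empty mask errors
  roi_empty <- matrix(0L, 2, 2)
  roi_empty[1, 1] <- 2L
  expect_error(extract_roi_spectra(cube, list(matrix(FALSE, 2, 2)),
                                   "RD-U", grid),
               "empty")
  # wrong-size mask errors
  expect_error(extract_roi_spectra(cube, list(matrix(TRUE, 3, 3)),
                                   "RD-U", grid),
               "edge|dimensions")
})

test_that("band trimming keeps the closed interval and is idempotent", {
  g <- wavelength_grid(c(900, 1000, 1800))
  sm <- spectra_matrix(matrix(1:6 / 10, 2, 3), g, c("RD-U", "RD-D"))
  tr <- trim_bands(sm, 930, 1700)
  expect_equal(tr$grid$centers, 1000)

  full <- trim_bands(sm, 900, 1800)
  expect_equal(full$grid$centers, g$centers)

  # idempotence
  tr2 <- trim_bands(tr, 930, 1700)
  expect_identical(tr2$reflectance, tr$reflectance)

  expect_error(trim_bands(sm, 1300, 1500), "no bands")
  expect_error(trim_bands(sm, 1500, 1300), "less than")

  # uniform 256-band grid over 874-1734 nm: closed-interval count is 228
  sm256 <- spectra_matrix(matrix(0.5, 1, 256), wavelength_grid(), "RD-U")
  expect_equal(trim_bands(sm256, 930, 1700)$grid$n, 228)
})

test_that("extraction commutes with band trimming", {
  sig <- make_class_signatures()
  sc <- generate_scene(tiny_config(seed = 8), sig)
  R <- calibrate_reflectance(sc$raw_cube, sc$dark_frame, sc$white_frame)
  sm_all <- extract_roi_spectra(R, sc$roi, sc$labels, sc$grid)
  a <- trim_bands(sm_all, 930, 1700)

  keep <- sc$grid$centers >= 930 & sc$grid$centers <= 1700
  sm_pre <- extract_roi_spectra(R[, , keep, drop = FALSE], sc$roi,
                                sc$labels,
                                wavelength_grid(sc$grid$centers[keep]))
  expect_equal(unname(a$reflectance), unname(sm_pre$reflectance),
               tolerance = 1e-12)
})
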