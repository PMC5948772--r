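test_that("class signatures show the expected absorption structure", {
  sig <- make_class_signatures(wavelength_grid(), 7)
  wl <- sig$grid$centers

  expect_equal(nrow(sig$reflectance), 7)
  expect_true(all(sig$reflectance > 0 & sig$reflectance < 1))

  # a local reflectance minimum within 1190-1230 nm for every class
  win <- which(wl >= 1150 & wl <= 1280)
  for (cls in 1:7) {
    curve <- sig$reflectance[cls, win]
    i_min <- which.min(curve)
    expect_gt(i_min, 1)
    expect_lt(i_min, length(win))
    valley <- wl[win][i_min]
    expect_true(valley >= 1190 && valley <= 1230)
  }

  # a deep water valley near 1450 nm for every class
  win45 <- which(wl >= 1400 & wl <= 1500)
  for (cls in 1:7) {
    i_min <- which.min(sig$reflectance[cls, win45])
    expect_true(abs(wl[win45][i_min] - 1450) < 30)
  }

  # 1210 nm feature depth grows monotonically with roasting degree
  expect_true(all(diff(sig$feature_1210_depth) > 0))
})

test_that("pairwise class separation peaks inside 930-1350 nm (exhaustive scan)", {
  sig <- make_class_signatures(wavelength_grid(), 7)
  wl <- sig$grid$centers
  for (i in 1:6) for (j in (i + 1):7) {
    d <- abs(sig$reflectance[i, ] - sig$reflectance[j, ])
    peak <- wl[which.max(d)]
    expect_true(peak >= 930 && peak <= 1350,
                info = sprintf("classes %d vs %d peak at %.0f nm",
                               i, j, peak))
  }
})

test_that("degenerate and invalid signature inputs behave as specified", {
  expect_error(make_class_signatures(n_classes = 1), "at least 2")
  flat <- default_features()
  flat$depth <- 0
  sig <- make_class_signatures(n_classes = 2, features = flat,
                               class_depth_step = 0, class_offset_step = 0)
  expect_equal(sig$reflectance[1, ], sig$baseline)
  expect_equal(sig$reflectance[2, ], sig$baseline)
})

test_that("scene generation is balanced, disjoint, seeded and size-checked", {
  sig <- make_class_signatures()
  cfg <- tiny_config(seed = 42)
  sc <- generate_scene(cfg, sig)

  expect_equal(as.vector(table(sc$labels)),
               rep(cfg$samples_per_class, cfg$n_classes))
  # integer-labelled ROI image implies disjoint masks; check coverage
  n <- cfg$n_classes * cfg$samples_per_class
  npix <- tabulate(sc$roi[sc$roi > 0], nbins = n)
  expect_true(all(npix == npix[1]))

  sc2 <- generate_scene(tiny_config(seed = 42), sig)
  expect_identical(sc$raw_cube, sc2$raw_cube)
  sc3 <- generate_scene(tiny_config(seed = 43), sig)
  expect_false(identical(sc$raw_cube, sc3$raw_cube))

  expect_error(generate_scene(tiny_config(image_height = 5,
                                          image_width = 5), sig),
               "too small")
})

test_that("noiseless scene calibration recovers each class signature exactly", {
  sig <- make_class_signatures()
  cfg <- tiny_config(noise_sd_interior = 0, noise_sd_edge = 0,
                     scatter_sd = 0, offset_sd = 0, seed = 3)
  sm <- calibrate_scene(generate_scene(cfg, sig))
  for (s in seq_along(sm$sample_ids)) {
    cls <- as.integer(sm$labels[s])
    expect_lt(max(abs(sm$reflectance[s, ] - sig$reflectance[cls, ])),
              1e-10)
  }
})

test_that("ROI-mean noise shrinks as 1/sqrt(pixels) (Monte-Carlo check)", {
  sig <- make_class_signatures()
  hits <- 0L; total <- 0L
  for (seed in 1:20) {
    cfg <- tiny_config(noise_sd_interior = 0.01,
                       noise_sd_edge = 0.01,
                       scatter_sd = 0, offset_sd = 0, seed = seed)
    sc <- generate_scene(cfg, sig)
    sm <- calibrate_scene(sc)
    npix <- sum(sc$roi == 1)
    bound <- 3 * 0.01 / sqrt(npix)
    dev <- abs(sm$reflectance[1, ] -
                 sig$reflectance[as.integer(sm$labels[1]), ])
    hits <- hits + sum(dev < bound)
    total <- total + length(dev)
  }
  expect_gte(hits / total, 0.99)
})

test_that("the fast spectra path matches its contract", {
  sig <- make_class_signatures()
  cfg <- scene_config(seed = 9)
  sm <- generate_spectra_matrix(cfg, sig)
  expect_equal(dim(sm), c(525, 256))
  expect_equal(as.vector(table(sm$labels)), rep(75, 7))

  # one sample per class, no randomness: rows equal the signatures
  cfg0 <- scene_config(samples_per_class = 1, noise_sd_interior = 0,
                       noise_sd_edge = 0, scatter_sd = 0, offset_sd = 0)
  sm0 <- generate_spectra_matrix(cfg0, sig)
  expect_equal(unname(sm0$reflectance), unname(sig$reflectance),
               tolerance = 1e-12)

  # determinism: same seed gives bit-identical output
  expect_identical(generate_spectra_matrix(cfg, sig)$reflectance,
                   sm$reflectance)
})

test_that("scene-then-extract equals the fast path in the noiseless limit", {
  sig <- make_class_signatures()
  # scatter kept non-zero: both paths must draw it identically
  cfg <- tiny_config(noise_sd_interior = 0, noise_sd_edge = 0,
                     scatter_sd = 0.02, offset_sd = 0.005, seed = 17)
  sm_scene <- calibrate_scene(generate_scene(cfg, sig))
  sm_fast <- generate_spectra_matrix(cfg, sig)
  expect_lt(max(abs(sm_scene$reflectance - sm_fast$reflectance)), 1e-10)
  expect_identical(sm_scene$labels, sm_fast$labels)
})

test_that("ENVI BIL round trip preserves the cube and grid", {
  sig <- make_class_signatures()
  sc <- generate_scene(tiny_config(seed = 5), sig)
  dir <- withr::local_tempdir()
  write_envi_cube(sc$raw_cube, sc$grid, file.path(dir, "cube"))
  back <- read_envi_cube(file.path(dir, "cube"))
  expect_identical(back$values, sc$raw_cube)
  expect_equal(back$grid$centers, sc$grid$centers, tolerance = 1e-6)

  write_scene(sc, file.path(dir, "scene"))
  sc2 <- read_scene(file.path(dir, "scene"))
  expect_identical(sc2$raw_cube, sc$raw_cube)
  expect_identical(sc2$roi, sc$roi)
  expect_equal(as.character(sc2$labels), as.character(sc$labels))
})
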