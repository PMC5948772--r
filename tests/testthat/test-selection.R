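test_that("X-loading selection picks the extrema of the loading curves", {
  # rank-1 data whose PC-1 loading is exactly a single Gaussian bump
  p <- 60
  bump <- exp(-((1:p) - 30)^2 / 20)
  set.seed(5)
  scores <- rnorm(40, sd = 2)
  X <- outer(scores, bump / sqrt(sum(bump^2)))
  m <- pca_fit(X, 1)
  g <- wavelength_grid(900 + (1:p) * 3)
  sel <- xloading_select(m, grid = g, n_components = 1, n_select = 3)
  expect_equal(sel$selected_indices[1], 30)

  # the bump is the only extremum: asking for more flags a short result
  short <- xloading_select(m, g, n_components = 1, n_select = 10)
  expect_true(short$short)
  expect_equal(short$selected_indices, 30)
})

test_that("X-loading selection recovers planted spectral features", {
  # 3 informative bands among noise; top selections should contain them
  hits <- 0L
  for (seed in 1:20) {
    d <- planted_spectra(n_per_class = 20, p = 80,
                         planted = c(15, 40, 65), effect_sd = 0.4,
                         noise_sd = 0.02, seed = seed)
    m <- pca_fit(d$X, 2)
    sel <- xloading_select(m, wavelength_grid(seq_len(80)),
                           n_components = 2, n_select = 3)
    if (all(d$planted %in% sel$selected_indices)) hits <- hits + 1L
  }
  expect_gte(hits, 18)
})

test_that("SPA projection chain behaves on orthogonal columns", {
  # orthogonal columns of norms 3 > 2 > 1: starting at the norm-3
  # column, projection removes nothing, so the norm-2 column is next
  X <- cbind(c(3, 0, 0), c(0, 2, 0), c(0, 0, 1))
  y <- c(1, 2, 3)
  chain <- roastspec:::spa_chain(X, 1, 3)
  expect_equal(chain$sel, c(1, 2, 3))
})

test_that("SPA chains match a from-scratch projection oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(12 * 6), 12, 6)
    for (start in 1:6) {
      fast <- roastspec:::spa_chain(X, start, 4)$sel
      expect_equal(fast, spa_chain_brute(X, start, 4),
                   info = sprintf("seed %d start %d", seed, start))
    }
  }
})

test_that("SPA is deterministic and recovers planted bands", {
  d <- planted_spectra(n_per_class = 25, p = 60,
                       planted = c(5, 20, 35, 50, 58), seed = 2)
  s1 <- spa_select(d$X, d$y, n_select = 5)
  s2 <- spa_select(d$X, d$y, n_select = 5)
  expect_identical(s1$selected_indices, s2$selected_indices)
  expect_gte(length(intersect(s1$selected_indices, d$planted)), 4)
  # selected list is in selection order: first pick has top importance
  expect_equal(order(s1$importance[s1$selected_indices],
                     decreasing = TRUE), 1:5)
})

test_that("random frog selection probabilities are valid and reproducible", {
  d <- planted_spectra(n_per_class = 10, p = 30,
                       planted = c(5, 15, 25), seed = 3)
  pars <- rf_params(T = 100, Q = 10, n_runs = 2, seed = 7)
  r1 <- random_frog(d$X, d$y, pars, n_select = 3)
  expect_true(all(r1$importance >= 0 & r1$importance <= 1))
  r2 <- random_frog(d$X, d$y, pars, n_select = 3)
  expect_identical(r1$importance, r2$importance)
  expect_error(random_frog(d$X, d$y, rf_params(Q = 50), n_select = 3),
               "Q must not exceed")
})

test_that("random frog concentrates probability on informative bands", {
  d <- planted_spectra(n_per_class = 20, p = 40,
                       planted = c(8, 16, 24, 32, 39),
                       effect_sd = 0.5, noise_sd = 0.01, seed = 5)
  sel <- random_frog(d$X, d$y, rf_params(T = 300, Q = 10, n_runs = 3,
                                         seed = 1), n_select = 5)
  expect_gte(length(intersect(sel$selected_indices, d$planted)), 4)
})

test_that("rf_params validates its scalar controls", {
  expect_error(rf_params(T = 0), "T must")
  expect_error(rf_params(theta = 0), "theta")
  expect_error(rf_params(eta = 0), "eta")
  expect_error(rf_params(eta = 1.5), "eta")
})

test_that("top_k truncates by importance, matching a sort oracle", {
  set.seed(9)
  sp <- runif(30)
  res <- selection_result("rf", sp, order(sp, decreasing = TRUE),
                          wavelength_grid(seq_len(30)))
  expect_identical(top_k(res, 30)$selected_indices,
                   res$selected_indices)
  expect_equal(top_k(res, 1)$selected_indices, which.max(sp))
  oracle <- sort(sp, decreasing = TRUE, index.return = TRUE)$ix[1:8]
  expect_equal(top_k(res, 8)$selected_indices, oracle)
  expect_error(top_k(res, 31), "k must lie")
})

test_that("all selectors stay on the trimmed grid", {
  sig <- make_class_signatures()
  sm <- trim_bands(generate_spectra_matrix(
    scene_config(samples_per_class = 8, seed = 21), sig))
  y <- as.numeric(as.integer(sm$labels))
  for (sel in list(
    xloading_select(pca_fit(sm, 2), n_select = 5),
    spa_select(sm, y, n_select = 3),
    random_frog(sm, y, rf_params(T = 50, Q = 20, n_runs = 1, seed = 2),
                n_select = 4))) {
    expect_true(all(sel$selected_wavelengths >= 930 &
                      sel$selected_wavelengths <= 1700))
  }
})
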