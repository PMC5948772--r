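test_that("RBF kernel matches its formula", {
  x <- matrix(rnorm(6), 3, 2)
  K <- rbf_kernel(x, x, 2)
  expect_equal(diag(K), rep(1, 3))
  # large width limit: kernel tends to 1 everywhere
  expect_true(all(abs(rbf_kernel(x, x, 1e12) - 1) < 1e-9))
  # hand-computed entries
  a <- matrix(c(0, 0, 1, 0, 0, 2), 3, 2, byrow = TRUE)
  K3 <- rbf_kernel(a, a, 1)
  expect_equal(K3[1, 2], exp(-1))
  expect_equal(K3[1, 3], exp(-4))
  expect_equal(K3[2, 3], exp(-5))
  expect_error(rbf_kernel(x, x, 0), "positive")
})

test_that("binary LS-SVM solves its KKT system and splits two points", {
  # two points, one per class: decision flips across the bisector
  X <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE)
  m <- lssvm_train_binary(X, c(-1, 1), 100, 1)
  expect_lt(predict(m, matrix(c(0, 0), 1)), 0)
  expect_gt(predict(m, matrix(c(2, 0), 1)), 0)
  # midpoint is on the boundary by symmetry
  expect_lt(abs(predict(m, matrix(c(1, 0), 1))), 1e-8)

  # KKT residual on random problems
  for (seed in 1:3) {
    set.seed(seed)
    Xr <- matrix(rnorm(40), 20, 2)
    yr <- rep(c(-1, 1), 10)
    mr <- lssvm_train_binary(Xr, yr, 10, 1.5)
    A <- rbf_kernel(Xr, Xr, 1.5) + diag(1 / 10, 20)
    kkt <- rbind(c(0, rep(1, 20)), cbind(1, A)) %*% c(mr$b, mr$alpha) -
      c(0, yr)
    expect_lt(max(abs(kkt)), 1e-8)
  }
  expect_error(lssvm_train_binary(X, c(1, 1), 10, 1), "both")
})

test_that("binary solution agrees with a generic dense solver", {
  set.seed(12)
  X <- matrix(rnorm(10), 5, 2)
  y <- c(-1, -1, 1, 1, 1)
  m <- lssvm_train_binary(X, y, 7, 2)
  M <- rbind(c(0, rep(1, 5)),
             cbind(1, rbf_kernel(X, X, 2) + diag(1 / 7, 5)))
  ref <- solve(M, c(0, y))
  expect_equal(m$b, ref[1], tolerance = 1e-8)
  expect_equal(m$alpha, ref[-1], tolerance = 1e-8)
})

test_that("multiclass one-vs-one reduces to binary and respects labels", {
  set.seed(2)
  X <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 4), 10, 2))
  lab <- rep(c("a", "b"), each = 10)
  mc <- lssvm_train_multiclass(X, lab, lssvm_params(gamma = 50))
  expect_length(mc$binaries, 1)
  pred <- predict(mc, X)
  bin <- predict(mc$binaries[[1]], X, type = "class")
  expect_equal(as.character(pred), ifelse(bin > 0, "a", "b"))
  # vote never leaves the codebook
  expect_true(all(pred %in% c("a", "b")))

  # permuting class names permutes predictions consistently
  lab2 <- c(a = "z2", b = "z1")[lab]
  mc2 <- lssvm_train_multiclass(X, lab2, lssvm_params(gamma = 50))
  expect_equal(c(a = "z2", b = "z1")[as.character(pred)],
               as.character(predict(mc2, X)), ignore_attr = TRUE)

  expect_error(lssvm_train_multiclass(X[1:11, ], c(rep("a", 10), "b"),
                                      lssvm_params()),
               "at least 2 samples")
})

test_that("duplicating every training sample leaves predictions unchanged", {
  set.seed(8)
  X <- matrix(rnorm(60), 30, 2)
  lab <- rep(c("a", "b", "c"), each = 10)
  p <- lssvm_params(gamma = 10, sigma2 = 1)
  m1 <- lssvm_train_multiclass(X, lab, p)
  m2 <- lssvm_train_multiclass(rbind(X, X), c(lab, lab), p)
  new <- matrix(rnorm(20), 10, 2)
  expect_equal(as.character(predict(m1, new)),
               as.character(predict(m2, new)))
})

test_that("interpolation limit: huge gamma drives training error to zero", {
  set.seed(4)
  X <- matrix(rnorm(40), 20, 2)   # distinct points, arbitrary labels
  y <- rep(c(-1, 1), 10)
  m <- lssvm_train_binary(X, y, 1e8, 0.5)
  expect_equal(predict(m, X, type = "class"), y)
})

test_that("tuning returns grid argmax with the documented tie-break", {
  set.seed(6)
  X <- rbind(matrix(rnorm(30, 0, 0.2), 15, 2),
             matrix(rnorm(30, 5, 0.2), 15, 2))
  lab <- rep(c("a", "b"), each = 15)

  # single-point grid is returned untouched
  p1 <- lssvm_params(gamma_grid = 42, sigma2_grid = 3, cv_folds = 3)
  t1 <- tune_lssvm(X, lab, p1)
  expect_equal(t1$gamma, 42)
  expect_equal(t1$sigma2, 3)

  # separable data: every gamma reaches 100%, tie-break picks gamma = 1
  p2 <- lssvm_params(gamma_grid = c(1, 10, 100), cv_folds = 3)
  t2 <- tune_lssvm(X, lab, p2)
  expect_equal(t2$gamma, 1)

  # argmax matches exhaustive recomputation of the CV table
  tab <- attr(t2, "cv_table")
  for (g in seq_len(nrow(tab))) {
    pg <- p2; pg$gamma <- tab$gamma[g]; pg$sigma2 <- tab$sigma2[g]
    expect_equal(lssvm_cross_validate(X, lab, pg), tab$accuracy[g])
  }
})

test_that("cross-validation is stratified, seeded and bounded", {
  set.seed(10)
  X <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
             matrix(rnorm(40, 6, 0.3), 20, 2))
  lab <- rep(c("a", "b"), each = 20)
  p <- lssvm_params(gamma = 10, cv_folds = 5, seed = 3)
  acc <- lssvm_cross_validate(X, lab, p)
  expect_equal(acc, 1)                    # separable data
  expect_identical(acc, lssvm_cross_validate(X, lab, p))  # same folds
  expect_error(lssvm_cross_validate(X, lab, p, folds = 25),
               "smallest class")
})
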