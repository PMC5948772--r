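#' Random frog parameters
#'
#' The five scalars steering the random-frog subset search plus the
#' repetition and inner-model settings. Defaults follow the standard
#' published settings: `T = 10000` iterations, initial subset size
#' `Q = 50`, proposal-variance control `theta = 0.3`, candidate-pool
#' coefficient `omega = 3`, acceptance upper bound `eta = 1`, and 50
#' averaged runs. For test-scale work a reduced profile
#' (`T = 1000`, `n_runs = 5`) is conventional.
#'
#' @param T Iterations per run (>= 1).
#' @param Q Initial subset size (1 <= Q <= p).
#' @param theta Proposal SD as a fraction of the current subset size
#'   (> 0).
#' @param omega Candidate-pool size coefficient (>= 1).
#' @param eta Upper bound of the acceptance probability, in (0, 1].
#' @param n_runs Independent runs whose selection probabilities are
#'   averaged.
#' @param inner_latent Cap on the latent variables of the inner PLS
#'   model (the effective count is also capped by the subset size).
#' @param cv_folds Folds of the inner cross-validated RMSE.
#' @param seed Integer seed; run r uses `seed + r - 1`.
#' @return An object of class `rf_params`.
#' @export
rf_params <- function(T = 10000, Q = 50, theta = 0.3, omega = 3,
                      eta = 1, n_runs = 50, inner_latent = 10,
                      cv_folds = 5, seed = 1) {
  if (T < 1) stop("T must be at least 1")
  if (Q < 1) stop("Q must be at least 1")
  if (theta <= 0) stop("theta must be positive")
  if (omega < 1) stop("omega must be at least 1")
  if (eta <= 0 || eta > 1) stop("eta must lie in (0, 1]")
  if (n_runs < 1) stop("n_runs must be at least 1")
  structure(list(T = as.integer(T), Q = as.integer(Q), theta = theta,
                 omega = omega, eta = eta, n_runs = as.integer(n_runs),
                 inner_latent = as.integer(inner_latent),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "rf_params")
}

#' Random frog wavelength selection
#'
#' Monte-Carlo subset search in the reversible-jump spirit with an inner
#' PLS1 model. One run performs `T` iterations: from the current subset
#' `V` a candidate size is drawn from `N(|V|, (theta * |V|)^2)`
#' (rounded, clamped to `[1, p]`). A smaller candidate keeps the bands
#' of `V` with the largest absolute PLS regression coefficients; a
#' larger one samples an `omega`-fold pool of outside bands, fits PLS on
#' the union and keeps the top bands by coefficient magnitude. The
#' candidate is accepted with probability
#' `min(eta, RMSE_current / RMSE_candidate)`, both RMSEs coming from a
#' k-fold cross-validated inner PLS on fixed folds; a candidate with a
#' non-finite RMSE is rejected. The inner model works on autoscaled
#' (unit-variance) columns so that coefficient magnitudes are
#' comparable across bands. Each band's selection probability (SP)
#' is the fraction of the `T` iterations whose retained subset contains
#' it; SPs are averaged over `n_runs` independent runs.
#'
#' @param x A [spectra_matrix()] or numeric matrix (typically the
#'   calibration rows only, to avoid leakage into later prediction).
#' @param y Numeric response (class dummy numbers), one per row.
#' @param params An [rf_params()] object.
#' @param n_select Number of top-SP bands reported (default 8).
#' @return A [selection_result()] with method `"rf"`; the importance
#'   vector is the mean SP in `[0, 1]`, `extra$sp_runs` the per-run SP
#'   matrix.
#' @export
random_frog <- function(x, y, params = rf_params(), n_select = 8) {
  X <- if (inherits(x, "spectra_matrix")) x$reflectance else as.matrix(x)
  grid <- if (inherits(x, "spectra_matrix")) x$grid
          else wavelength_grid(seq_len(ncol(X)))
  y <- as.numeric(y)
  stopifnot(inherits(params, "rf_params"))
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("y must align with the rows of x")
  if (params$Q > p) stop("Q must not exceed the number of bands")
  if (n_select > p) stop("n_select must not exceed the number of bands")

  sp <- matrix(NA_real_, p, params$n_runs)
  for (r in seq_len(params$n_runs))
    sp[, r] <- rf_one_run(X, y, params, params$seed + r - 1L)
  sp_mean <- rowMeans(sp)

  sel <- order(sp_mean, decreasing = TRUE)[seq_len(n_select)]
  selection_result("rf", sp_mean, sel, grid,
                   extra = list(sp_runs = sp))
}

rf_one_run <- function(X, y, params, seed) {
  n <- nrow(X); p <- ncol(X)
  # autoscale columns for the inner model so PLS coefficient magnitudes
  # are comparable across bands of different variance (constant bands
  # are zeroed out and can never look informative)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- Inf
  X <- scale(X, center = TRUE, scale = sds)
  set.seed(seed)
  fold_id <- make_folds(n, params$cv_folds)
  V <- sort(sample.int(p, params$Q))
  counts <- numeric(p)

  cv <- function(vars) {
    a <- min(params$inner_latent, length(vars), n - ceiling(n / params$cv_folds) - 1)
    if (a < 1) return(Inf)
    pls_cv_rmse(X[, vars, drop = FALSE], y, a, fold_id)
  }
  coef_rank <- function(vars) {
    a <- max(1L, min(params$inner_latent, length(vars), n - 1L))
    cf <- pls1_coef_cpp(X[, vars, drop = FALSE], y, a)[-1]
    vars[order(abs(cf), decreasing = TRUE)]
  }

  rmse_V <- cv(V)
  for (t in seq_len(params$T)) {
    nV <- length(V)
    n_star <- round(stats::rnorm(1, nV, params$theta * nV))
    n_star <- max(1L, min(p, as.integer(n_star)))
    if (n_star == nV) {
      V_star <- V
      rmse_star <- rmse_V
    } else if (n_star < nV) {
      V_star <- sort(coef_rank(V)[seq_len(n_star)])
      rmse_star <- cv(V_star)
    } else {
      outside <- setdiff(seq_len(p), V)
      pool_size <- min(length(outside),
                       round(params$omega * (n_star - nV)))
      pool <- if (pool_size > 0) sample(outside, pool_size) else integer(0)
      cand <- c(V, pool)
      n_star <- min(n_star, length(cand))
      V_star <- sort(coef_rank(cand)[seq_len(n_star)])
      rmse_star <- cv(V_star)
    }
    accept <- if (!is.finite(rmse_star)) FALSE
              else if (rmse_star <= 0) TRUE
              else stats::runif(1) <= min(params$eta, rmse_V / rmse_star)
    if (accept) {
      V <- V_star
      rmse_V <- rmse_star
    }
    counts[V] <- counts[V] + 1
  }
  counts / params$T
}
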