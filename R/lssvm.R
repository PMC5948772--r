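#' RBF (Gaussian) kernel matrix
#'
#' `K[i, j] = exp(-||a_i - b_j||^2 / sigma2)`.
#'
#' @param X_a,X_b Numeric matrices with matching column counts.
#' @param sigma2 Kernel width parameter (> 0).
#' @return The `nrow(X_a)` x `nrow(X_b)` kernel matrix.
#' @export
rbf_kernel <- function(X_a, X_b, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  X_a <- as.matrix(X_a); X_b <- as.matrix(X_b)
  if (ncol(X_a) != ncol(X_b)) stop("column counts must match")
  d2 <- outer(rowSums(X_a^2), rowSums(X_b^2), `+`) -
    2 * tcrossprod(X_a, X_b)
  d2[d2 < 0] <- 0
  exp(-d2 / sigma2)
}

#' Median-heuristic kernel width
#'
#' The median of the pairwise squared Euclidean distances between rows -
#' the standard default for the RBF width when only the regularization
#' parameter is tuned.
#'
#' @param X Numeric matrix (rows = samples).
#' @return A positive scalar.
#' @export
median_heuristic <- function(X) {
  d2 <- as.numeric(stats::dist(as.matrix(X)))^2
  m <- stats::median(d2)
  if (!is.finite(m) || m <= 0) 1 else m
}

#' LS-SVM hyperparameters
#'
#' @param gamma Regularization parameter; the conventional search range
#'   is \[1, 1000\].
#' @param sigma2 RBF width; `NULL` means use the median heuristic of the
#'   training rows.
#' @param gamma_grid Grid for [tune_lssvm()]; default 100 log-spaced
#'   points in \[1, 1000\] (a pointwise discretisation of that range).
#' @param sigma2_grid Optional grid of widths; `NULL` keeps the single
#'   median-heuristic value.
#' @param cv_folds Folds for tuning / internal validation (default 10).
#' @param seed Seed for fold construction.
#' @return An object of class `lssvm_params`.
#' @export
lssvm_params <- function(gamma = 1, sigma2 = NULL,
                         gamma_grid = 10^seq(0, 3, length.out = 100),
                         sigma2_grid = NULL,
                         cv_folds = 10, seed = 1) {
  if (gamma <= 0) stop("gamma must be positive")
  if (!is.null(sigma2) && sigma2 <= 0) stop("sigma2 must be positive")
  if (length(gamma_grid) < 1) stop("gamma_grid must be non-empty")
  structure(list(gamma = gamma, sigma2 = sigma2,
                 gamma_grid = sort(gamma_grid),
                 sigma2_grid = if (is.null(sigma2_grid)) NULL
                               else sort(sigma2_grid),
                 cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "lssvm_params")
}

#' Train a binary LS-SVM
#'
#' Solves the least-squares SVM dual system directly: with
#' `A = K + I / gamma`, the bias is `b = (1' A^-1 y) / (1' A^-1 1)` and
#' the dual coefficients are `alpha = A^-1 (y - b)`, which together
#' satisfy the KKT system `[[0, 1'], [1, A]] [b; alpha] = [0; y]`.
#'
#' @param X Training rows.
#' @param y Labels in `{-1, +1}` (both classes present).
#' @param gamma Regularization parameter.
#' @param sigma2 RBF width.
#' @return An object of class `lssvm_binary` holding the training rows,
#'   `alpha`, `b` and the kernel parameters.
#' @export
lssvm_train_binary <- function(X, y, gamma, sigma2) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2)
    stop("y must contain both -1 and +1")
  K <- rbf_kernel(X, X, sigma2)
  A <- K + diag(1 / gamma, nrow(X))
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch))
    stop(sprintf("singular LS-SVM system (condition number %.3g)",
                 kappa(A)))
  Ainv_y <- backsolve(ch, forwardsolve(t(ch), y))
  Ainv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, nrow(X))))
  b <- sum(Ainv_y) / sum(Ainv_1)
  alpha <- Ainv_y - b * Ainv_1
  structure(list(X = X, y = y, alpha = alpha, b = b,
                 gamma = gamma, sigma2 = sigma2),
            class = "lssvm_binary")
}

#' @param object A fitted `lssvm_binary`.
#' @param newdata Matrix of new rows.
#' @param type `"decision"` for the raw decision value, `"class"` for
#'   its sign.
#' @param ... Unused.
#' @rdname lssvm_train_binary
#' @export
predict.lssvm_binary <- function(object, newdata,
                                 type = c("decision", "class"), ...) {
  type <- match.arg(type)
  f <- drop(rbf_kernel(as.matrix(newdata), object$X, object$sigma2) %*%
              object$alpha) + object$b
  if (type == "class") ifelse(f >= 0, 1, -1) else f
}

#' Train a multiclass LS-SVM (one-vs-one)
#'
#' Fits one binary LS-SVM per unordered class pair and predicts by
#' majority vote; ties are broken by the summed decision values
#' accumulated for each class across its pairwise models. The RBF width
#' defaults to the median heuristic of the training rows when
#' `params$sigma2` is `NULL`.
#'
#' @param x A [spectra_matrix()] or numeric matrix.
#' @param labels Class labels, one per row; every class needs at least
#'   2 samples.
#' @param params An [lssvm_params()].
#' @return An object of class `lssvm_model`.
#' @export
lssvm_train_multiclass <- function(x, labels, params = lssvm_params()) {
  X <- if (inherits(x, "spectra_matrix")) x$reflectance else as.matrix(x)
  labels <- as.factor(labels)
  if (length(labels) != nrow(X)) stop("one label per row required")
  lev <- levels(labels)
  if (length(lev) < 2) stop("need at least 2 classes")
  if (any(table(labels) < 2))
    stop("every class needs at least 2 samples")
  sigma2 <- if (is.null(params$sigma2)) median_heuristic(X)
            else params$sigma2
  pairs <- utils::combn(length(lev), 2)
  binaries <- vector("list", ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1, m]; j <- pairs[2, m]
    rows <- which(labels %in% lev[c(i, j)])
    yb <- ifelse(labels[rows] == lev[i], 1, -1)
    binaries[[m]] <- lssvm_train_binary(X[rows, , drop = FALSE], yb,
                                        params$gamma, sigma2)
  }
  structure(list(binaries = binaries, pairs = pairs, levels = lev,
                 gamma = params$gamma, sigma2 = sigma2),
            class = "lssvm_model")
}

#' @param object A fitted `lssvm_model`.
#' @param newdata Matrix or `spectra_matrix` of new rows.
#' @param ... Unused.
#' @rdname lssvm_train_multiclass
#' @export
predict.lssvm_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectra_matrix")) newdata$reflectance
       else as.matrix(newdata)
  nl <- length(object$levels)
  votes <- matrix(0, nrow(X), nl)
  scores <- matrix(0, nrow(X), nl)
  for (m in seq_along(object$binaries)) {
    i <- object$pairs[1, m]; j <- object$pairs[2, m]
    f <- predict(object$binaries[[m]], X)
    win_i <- f >= 0
    votes[, i] <- votes[, i] + win_i
    votes[, j] <- votes[, j] + !win_i
    scores[, i] <- scores[, i] + f
    scores[, j] <- scores[, j] - f
  }
  pick <- integer(nrow(X))
  for (r in seq_len(nrow(X))) {
    best <- which(votes[r, ] == max(votes[r, ]))
    if (length(best) > 1)
      best <- best[which.max(scores[r, best])]
    pick[r] <- best[1]
  }
  factor(object$levels[pick], levels = object$levels)
}

# stratified fold ids: within each class, shuffle rows and deal them out
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (lv in levels(as.factor(labels))) {
    idx <- which(labels == lv)
    fold[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

#' Stratified cross-validated accuracy of a multiclass LS-SVM
#'
#' Folds are stratified by class and seeded; the returned accuracy is
#' the pooled fraction of correctly classified held-out samples (i.e.
#' fold accuracies weighted by fold size).
#'
#' @param x Predictor rows.
#' @param labels Class labels.
#' @param params An [lssvm_params()]; `cv_folds` and `seed` control the
#'   folds.
#' @param folds Number of folds (default `params$cv_folds`).
#' @return Accuracy fraction in \[0, 1\].
#' @export
lssvm_cross_validate <- function(x, labels, params = lssvm_params(),
                                 folds = params$cv_folds) {
  X <- if (inherits(x, "spectra_matrix")) x$reflectance else as.matrix(x)
  labels <- as.factor(labels)
  if (folds < 2) stop("folds must be at least 2")
  if (folds > min(table(labels)))
    stop("folds exceed the smallest class count")
  fold <- stratified_folds(labels, folds, params$seed)
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f
    model <- lssvm_train_multiclass(X[tr, , drop = FALSE], labels[tr],
                                    params)
    pred <- predict(model, X[!tr, , drop = FALSE])
    correct <- correct + sum(pred == labels[!tr])
  }
  correct / length(labels)
}

#' Tune LS-SVM hyperparameters by grid search
#'
#' Pointwise search: every `(gamma, sigma2)` grid point is scored by
#' stratified k-fold cross-validated accuracy on the provided rows, and
#' the argmax is returned (ties resolved toward the smallest `gamma`,
#' then the smallest `sigma2`).
#'
#' @param x Predictor rows (typically the calibration set).
#' @param labels Class labels.
#' @param params An [lssvm_params()] whose `gamma_grid` / `sigma2_grid`
#'   define the search space; a `NULL` `sigma2_grid` searches only the
#'   median-heuristic width.
#' @return An `lssvm_params` with `gamma` and `sigma2` set to the
#'   winning point; the full CV table is attached as attribute
#'   `"cv_table"`.
#' @export
tune_lssvm <- function(x, labels, params = lssvm_params()) {
  X <- if (inherits(x, "spectra_matrix")) x$reflectance else as.matrix(x)
  labels <- as.factor(labels)
  s2_grid <- if (is.null(params$sigma2_grid)) median_heuristic(X)
             else params$sigma2_grid
  grid <- expand.grid(gamma = params$gamma_grid, sigma2 = s2_grid)
  grid$accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    p_g <- params
    p_g$gamma <- grid$gamma[g]
    p_g$sigma2 <- grid$sigma2[g]
    grid$accuracy[g] <- lssvm_cross_validate(X, labels, p_g)
  }
  # argmax with ties toward smallest gamma, then smallest sigma2
  ord <- order(-grid$accuracy, grid$gamma, grid$sigma2)
  best <- grid[ord[1], ]
  out <- params
  out$gamma <- best$gamma
  out$sigma2 <- best$sigma2
  attr(out, "cv_table") <- grid
  out
}
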