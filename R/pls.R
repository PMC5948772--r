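#' PLS1 regression (NIPALS)
#'
#' Single-response partial least squares regression fitted by the NIPALS
#' recursion on column-centered data. With the full latent dimension
#' (the rank of the centered predictor matrix) the fit coincides with
#' ordinary least squares; with fewer latent variables it is the usual
#' shrunken PLS fit used as the inner model of subset-search wavelength
#' selection.
#'
#' @param x A [spectra_matrix()] or numeric matrix of predictors.
#' @param y Numeric response, one value per row (e.g. roasting-degree
#'   dummy numbers 1..7).
#' @param n_latent Number of latent variables; at most `min(n - 1, p)`.
#' @return An object of class `pls1_model`: `coefficients` (length p),
#'   `intercept`, `n_latent`, and the fitted training values.
#' @examples
#' X <- matrix(rnorm(50), 10, 5)
#' y <- X[, 2] * 3 + 1
#' m <- pls1_fit(X, y, 1)
#' rmse(y, predict(m, X))
#' @export
pls1_fit <- function(x, y, n_latent) {
  X <- if (inherits(x, "spectra_matrix")) x$reflectance else as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("y must have one value per row of x")
  if (stats::sd(y) == 0) stop("y has zero variance")
  if (n_latent < 1 || n_latent > min(n - 1, p))
    stop("n_latent must lie in [1, min(n - 1, p)] = [1, ", min(n - 1, p), "]")
  cf <- pls1_coef_cpp(X, y, as.integer(n_latent))
  m <- structure(list(coefficients = cf[-1], intercept = cf[1],
                      n_latent = as.integer(n_latent)),
                 class = "pls1_model")
  m$fitted <- predict(m, X)
  m
}

#' @param object A `pls1_model`.
#' @param newdata Matrix (or `spectra_matrix`) of new rows.
#' @param ... Unused.
#' @rdname pls1_fit
#' @export
predict.pls1_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectra_matrix")) newdata$reflectance
       else as.matrix(newdata)
  drop(X %*% object$coefficients) + object$intercept
}

#' Root mean squared error
#'
#' @param y_true,y_pred Numeric vectors of equal, positive length.
#' @return `sqrt(mean((y_true - y_pred)^2))`.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (length(y_true) == 0) stop("empty input")
  sqrt(mean((y_true - y_pred)^2))
}

# k-fold CV RMSE of a PLS1 model on given columns; fold ids fixed by caller
pls_cv_rmse <- function(X, y, n_latent, fold_id) {
  n_latent <- max(1L, as.integer(n_latent))
  pls1_cv_rmse_cpp(X, y, n_latent, as.integer(fold_id))
}

# cyclic fold assignment after a seeded shuffle
make_folds <- function(n, k) {
  sample(rep(seq_len(k), length.out = n))
}
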