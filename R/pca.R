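#' Principal component analysis of a spectra matrix
#'
#' Column-mean-centered PCA computed through the singular value
#' decomposition (numerically stable; no covariance matrix is formed).
#' The sign of each component is fixed so that its largest-magnitude
#' loading element is positive, making loading plots reproducible.
#'
#' @param x A [spectra_matrix()] or numeric matrix (rows = samples).
#' @param k Number of components to keep (default `min(n, p)`).
#' @return An object of class `pca_model`: `mean_spectrum`, `loadings`
#'   (p x k, orthonormal columns), `scores` (n x k),
#'   `explained_variance_fraction` (length k, non-increasing) and, when
#'   available, the wavelength `grid`.
#' @examples
#' X <- matrix(rnorm(40), 8, 5)
#' m <- pca_fit(X, 2)
#' m$explained_variance_fraction
#' @export
pca_fit <- function(x, k = NULL) {
  X <- if (inherits(x, "spectra_matrix")) x$reflectance else as.matrix(x)
  grid <- if (inherits(x, "spectra_matrix")) x$grid else NULL
  n <- nrow(X); p <- ncol(X)
  if (anyNA(X) || any(!is.finite(X))) stop("data must be finite")
  if (is.null(k)) k <- min(n, p)
  if (k < 1 || k > min(n, p))
    stop("k must lie in [1, min(n, p)] = [1, ", min(n, p), "]")

  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  total <- sum(sv$d^2)
  explained <- if (total < 1e-300) rep(0, k) else (sv$d^2 / total)[seq_len(k)]

  loadings <- sv$v[, seq_len(k), drop = FALSE]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  if (total < 1e-300) scores[] <- 0
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(mean_spectrum = mu, loadings = loadings, scores = scores,
                 explained_variance_fraction = explained,
                 k = k, grid = grid),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components; first explains %.2f%%\n",
              x$k, 100 * x$explained_variance_fraction[1]))
  invisible(x)
}
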