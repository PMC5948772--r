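#' Successive projections algorithm (SPA) wavelength selection
#'
#' Forward selection designed to minimise collinearity: starting from a
#' candidate band, each step projects all remaining band columns onto
#' the orthogonal complement of the span of the bands already chosen and
#' picks the column with the largest residual norm. Every band is tried
#' as the chain start; each resulting chain of `n_select` bands is
#' scored by the RMSE of a multiple linear regression predicting the
#' class response on a held-out validation split (a Kennard-Stone
#' partition of the provided rows, so the scoring is deterministic), and
#' the best-scoring chain is returned in selection order.
#'
#' @param x A [spectra_matrix()] or numeric matrix.
#' @param y Numeric response (class dummy numbers), one per row.
#' @param n_select Chain length (default 5).
#' @param validation_fraction Fraction of rows held out for chain
#'   scoring (default 1/3, i.e. a 2:1 split).
#' @param starts Candidate starting bands (default: all bands).
#' @return A [selection_result()] with method `"spa"`. The importance
#'   vector ranks selected bands by selection order (first pick
#'   highest); unselected bands score 0. `extra$rmse` holds the winning
#'   chain's validation RMSE and `extra$start` its starting band.
#' @export
spa_select <- function(x, y, n_select = 5, validation_fraction = 1 / 3,
                       starts = NULL) {
  X <- if (inherits(x, "spectra_matrix")) x$reflectance else as.matrix(x)
  grid <- if (inherits(x, "spectra_matrix")) x$grid
          else wavelength_grid(seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("y must align with the rows of x")
  if (n_select < 1 || n_select > p)
    stop("n_select must lie in [1, p]")
  if (is.null(starts)) starts <- seq_len(p)

  split <- kennard_stone_split(X, 1 - validation_fraction)
  cal <- split$calibration; val <- split$prediction

  best <- NULL
  for (j in starts) {
    chain <- spa_chain(X[cal, , drop = FALSE], j, n_select)
    score <- spa_score(X, y, cal, val, chain$sel)
    if (is.null(best) || (is.finite(score) && score < best$score)) {
      best <- list(sel = chain$sel, score = score, start = j,
                   short = chain$short)
    }
  }
  if (is.null(best) || !is.finite(best$score))
    stop("no SPA chain produced a finite validation RMSE")

  importance <- rep(0, p)
  importance[best$sel] <- rev(seq_along(best$sel))
  selection_result("spa", importance, best$sel, grid,
                   short = best$short,
                   extra = list(rmse = best$score, start = best$start))
}

# one projection chain: Gram-Schmidt on the columns of Xcal
spa_chain <- function(Xcal, start, n_select, tol = 1e-10) {
  p <- ncol(Xcal)
  P <- Xcal                      # residual columns
  sel <- start
  short <- FALSE
  for (step in seq_len(n_select - 1)) {
    v <- P[, sel[length(sel)]]
    nv2 <- sum(v^2)
    if (nv2 < tol) { short <- TRUE; break }   # degenerate direction
    proj <- crossprod(P, v) / nv2             # p x 1
    P <- P - tcrossprod(v, drop(proj))
    norms <- colSums(P^2)
    norms[sel] <- -Inf
    nxt <- which.max(norms)
    if (norms[nxt] < tol) { short <- TRUE; break }
    sel <- c(sel, nxt)
  }
  list(sel = sel, short = short)
}

# hold-out RMSE of an intercept MLR on the selected columns
spa_score <- function(X, y, cal, val, sel) {
  Xtr <- cbind(1, X[cal, sel, drop = FALSE])
  beta <- tryCatch(qr.solve(Xtr, y[cal]), error = function(e) NULL)
  if (is.null(beta)) return(Inf)
  pred <- drop(cbind(1, X[val, sel, drop = FALSE]) %*% beta)
  rmse(y[val], pred)
}
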