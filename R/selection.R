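#' Effective-wavelength selection result
#'
#' Common container returned by the three selectors: a per-band
#' importance score (selection probability for random frog, absolute
#' loading for X-loading extrema, selection-order rank for SPA) and the
#' chosen bands ordered by decreasing importance.
#'
#' @param method One of `"xloading"`, `"spa"`, `"rf"`.
#' @param importance Numeric vector, one score per band of `grid`.
#' @param selected_indices Integer band indices, ordered by importance.
#' @param grid The [wavelength_grid()] the selection refers to.
#' @param short Logical flag: fewer candidates were available than
#'   requested.
#' @param extra Optional list of method-specific diagnostics.
#' @return An object of class `selection_result`.
#' @export
selection_result <- function(method, importance, selected_indices, grid,
                             short = FALSE, extra = list()) {
  grid <- as_wavelength_grid(grid)
  stopifnot(length(importance) == grid$n,
            all(selected_indices >= 1), all(selected_indices <= grid$n))
  structure(list(method = method,
                 importance = importance,
                 selected_indices = as.integer(selected_indices),
                 selected_wavelengths = grid$centers[selected_indices],
                 grid = grid, short = short, extra = extra),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method=%s, %d bands: %s nm\n",
              x$method, length(x$selected_indices),
              paste(round(x$selected_wavelengths), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.selection_result <- function(x, ...) {
  rank <- match(seq_len(x$grid$n), x$selected_indices)
  data.frame(wavelength_nm = x$grid$centers,
             importance = x$importance,
             rank = rank,
             method = x$method)
}

#' Keep the top-k bands of a selection result
#'
#' Truncates the ordered selection to its `k` most important bands; with
#' `k` at least the current selection length the result is unchanged.
#'
#' @param result A [selection_result()].
#' @param k Number of bands to keep (`k <=` number of grid bands).
#' @return A `selection_result` with at most `k` selected bands.
#' @export
top_k <- function(result, k) {
  stopifnot(inherits(result, "selection_result"))
  if (k < 1 || k > result$grid$n)
    stop("k must lie in [1, ", result$grid$n, "]")
  keep <- result$selected_indices[seq_len(min(k, length(result$selected_indices)))]
  selection_result(result$method, result$importance, keep, result$grid,
                   short = result$short, extra = result$extra)
}

#' Plot a selection result
#'
#' Importance versus wavelength with the selected bands marked.
#'
#' @param x A `selection_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.selection_result <- function(x, ...) {
  graphics::plot(x$grid$centers, x$importance, type = "l",
                 xlab = "wavelength (nm)",
                 ylab = switch(x$method, rf = "selection probability",
                               xloading = "|X-loading|", "importance"),
                 main = sprintf("%s selection", x$method), ...)
  graphics::abline(v = x$selected_wavelengths, col = "firebrick",
                   lty = 3)
  invisible(x)
}

#' Write a selection result as CSV
#'
#' @param result A `selection_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_selection_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}

#' X-loading extrema wavelength selection
#'
#' Operationalises "pick the bands with large absolute principal-
#' component loadings": for each of the first `n_components` components
#' the local maxima of the absolute loading curve are found (interior
#' bands only), pooled across components (keeping, per band, the largest
#' absolute loading), and the `n_select` pooled extrema with the largest
#' scores are returned. If fewer extrema exist than requested, all are
#' returned and the result is flagged `short`.
#'
#' @param pca A [pca_fit()] model.
#' @param grid Wavelength grid; defaults to the grid stored in `pca`.
#' @param n_components Number of leading components to scan (default 2).
#' @param n_select Number of bands to return (default 7).
#' @return A [selection_result()] with method `"xloading"`; the
#'   importance vector holds, per band, the maximum absolute loading
#'   over the scanned components.
#' @export
xloading_select <- function(pca, grid = pca$grid, n_components = 2,
                            n_select = 7) {
  stopifnot(inherits(pca, "pca_model"))
  if (is.null(grid)) stop("no wavelength grid available")
  grid <- as_wavelength_grid(grid)
  if (n_components > pca$k)
    stop("pca holds only ", pca$k, " components")
  p <- grid$n
  stopifnot(p == nrow(pca$loadings))

  importance <- rep(0, p)
  pool_idx <- integer(0)
  pool_val <- numeric(0)
  for (j in seq_len(n_components)) {
    a <- abs(pca$loadings[, j])
    importance <- pmax(importance, a)
    ext <- local_maxima(a)
    pool_idx <- c(pool_idx, ext)
    pool_val <- c(pool_val, a[ext])
  }
  # de-duplicate across components, keeping the larger score per band
  o <- order(pool_val, decreasing = TRUE)
  pool_idx <- pool_idx[o]; pool_val <- pool_val[o]
  keep <- !duplicated(pool_idx)
  pool_idx <- pool_idx[keep]
  short <- length(pool_idx) < n_select
  sel <- pool_idx[seq_len(min(n_select, length(pool_idx)))]
  selection_result("xloading", importance, sel, grid, short = short)
}

# interior local maxima of a curve (strict rise on the left, non-strict
# fall on the right so plateau edges count once)
local_maxima <- function(a) {
  p <- length(a)
  if (p < 3) return(integer(0))
  i <- 2:(p - 1)
  i[a[i] > a[i - 1] & a[i] >= a[i + 1]]
}
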