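#' Construct a spectra matrix
#'
#' The central tabular container of the workflow: one row per sample, one
#' column per spectral band, with the wavelength grid, a roasting-degree
#' label per row and stable sample identifiers.
#'
#' @param reflectance Numeric matrix, samples x bands.
#' @param grid A [wavelength_grid()] whose length matches `ncol(reflectance)`.
#' @param labels Factor (or coercible) of class labels, one per row.
#' @param sample_ids Optional character ids, one per row.
#' @return An object of class `spectra_matrix`.
#' @export
spectra_matrix <- function(reflectance, grid, labels,
                           sample_ids = NULL) {
  grid <- as_wavelength_grid(grid)
  reflectance <- as.matrix(reflectance)
  if (ncol(reflectance) != grid$n)
    stop("reflectance has ", ncol(reflectance),
         " columns but the grid has ", grid$n, " bands")
  if (anyNA(reflectance) || any(!is.finite(reflectance)))
    stop("reflectance must be finite with no missing values")
  labels <- as.factor(labels)
  if (length(labels) != nrow(reflectance))
    stop("need one label per row")
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%04d", seq_len(nrow(reflectance)))
  if (length(sample_ids) != nrow(reflectance))
    stop("need one sample id per row")
  dimnames(reflectance) <- list(sample_ids,
                                sprintf("%.2f", grid$centers))
  structure(list(reflectance = reflectance, grid = grid,
                 labels = labels, sample_ids = sample_ids),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("<spectra_matrix> %d samples x %d bands (%.1f-%.1f nm), %d classes\n",
              nrow(x$reflectance), x$grid$n, min(x$grid$centers),
              max(x$grid$centers), nlevels(x$labels)))
  invisible(x)
}

#' @export
dim.spectra_matrix <- function(x) dim(x$reflectance)

#' Subset a spectra matrix by rows
#'
#' @param x A `spectra_matrix`.
#' @param i Row indices.
#' @param ... Unused.
#' @return A `spectra_matrix` with the selected rows.
#' @export
`[.spectra_matrix` <- function(x, i, ...) {
  spectra_matrix(x$reflectance[i, , drop = FALSE], x$grid,
                 droplevels(x$labels[i]), x$sample_ids[i])
}

#' Write / read a spectra matrix as CSV
#'
#' The CSV layout is one row per sample with columns `sample_id`, `label`,
#' then one column per band named by its wavelength in nm.
#'
#' @param x A `spectra_matrix`.
#' @param path File path.
#' @return `write_spectra_csv` returns `path` invisibly;
#'   `read_spectra_csv` returns a `spectra_matrix`.
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectra_matrix"))
  df <- data.frame(sample_id = x$sample_ids,
                   label = as.character(x$labels),
                   x$reflectance, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  bands <- setdiff(names(df), c("sample_id", "label"))
  spectra_matrix(as.matrix(df[bands]),
                 wavelength_grid(as.numeric(bands)),
                 df$label, df$sample_id)
}

# numeric class response ("dummy numbers"): ordinal 1..k in roasting order
class_response <- function(labels) as.numeric(as.integer(as.factor(labels)))
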