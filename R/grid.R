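#' Wavelength grid of an imaging spectrograph
#'
#' A wavelength grid holds the band-center wavelengths (nm) of a
#' line-scan spectrograph. The default emulates a 256-band NIR instrument
#' spanning 874-1734 nm with uniformly spaced centers; real instruments
#' publish a slightly non-uniform band-center table, which can be passed
#' directly.
#'
#' @param centers Numeric vector of band centers in nm, strictly increasing.
#' @return An object of class `wavelength_grid` with elements `centers`
#'   and `n`.
#' @examples
#' g <- wavelength_grid()
#' g$n
#' range(g$centers)
#' @export
wavelength_grid <- function(centers = seq(874, 1734, length.out = 256)) {
  if (!is.numeric(centers) || length(centers) < 1 || anyNA(centers))
    stop("band centers must be a non-empty numeric vector without NA")
  centers <- as.numeric(centers)
  if (length(centers) > 1 && any(diff(centers) <= 0))
    stop("band centers must be strictly increasing")
  structure(list(centers = centers, n = length(centers)),
            class = "wavelength_grid")
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %d bands, %.1f-%.1f nm\n",
              x$n, min(x$centers), max(x$centers)))
  invisible(x)
}

as_wavelength_grid <- function(x) {
  if (inherits(x, "wavelength_grid")) return(x)
  wavelength_grid(x)
}

#' Roasting-degree class labels
#'
#' Standard ordinal labels for coffee roasting degrees, from unroasted
#' (RD-U) through light, moderately light, light medium, medium and
#' moderately dark to dark (RD-D). For class counts other than seven,
#' generic ordered labels are generated.
#'
#' @param n_classes Number of roasting-degree classes.
#' @return Character vector of length `n_classes`, in roasting order.
#' @export
roast_labels <- function(n_classes = 7) {
  if (n_classes == 7)
    c("RD-U", "RD-L", "RD-ML", "RD-LM", "RD-M", "RD-MD", "RD-D")
  else
    sprintf("RD-%02d", seq_len(n_classes))
}
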