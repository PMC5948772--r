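#' Reflectance calibration against dark and white references
#'
#' Converts a raw digital-number hypercube to relative reflectance using
#' the standard white-dark correction
#' `R = (I_raw - I_dark) / (I_white - I_dark)` applied elementwise.
#' Reference frames may be full cubes with the same dimensions as
#' `raw_cube`, or single-line frames (pixels x bands) that are broadcast
#' along the scan axis - the natural form for a line-scan spectrograph
#' whose references are acquired once per line position.
#'
#' @param raw_cube 3-D numeric array, lines x pixels x bands.
#' @param dark_frame,white_frame Reference frames: arrays of the same
#'   dimension as `raw_cube`, or matrices of dimension pixels x bands.
#' @return A 3-D reflectance array of the same dimension as `raw_cube`
#'   (class `reflectance_cube`). Values are typically in \[0, 1\] but may
#'   slightly exceed that range under noise.
#' @examples
#' raw <- array(50, c(2, 2, 3))
#' calibrate_reflectance(raw, array(10, dim(raw)), array(90, dim(raw)))[1]
#' @export
calibrate_reflectance <- function(raw_cube, dark_frame, white_frame) {
  d <- dim(raw_cube)
  if (length(d) != 3) stop("raw_cube must be a 3-D array")
  dark <- broadcast_frame(dark_frame, d, "dark_frame")
  white <- broadcast_frame(white_frame, d, "white_frame")
  denom <- white - dark
  bad <- which(denom <= 0)
  if (length(bad)) {
    at <- arrayInd(bad[1], d)
    stop(sprintf(paste0("white_frame must exceed dark_frame everywhere; ",
                        "first violation at line %d, pixel %d, band %d"),
                 at[1], at[2], at[3]))
  }
  R <- (raw_cube - dark) / denom
  class(R) <- c("reflectance_cube", class(R))
  R
}

# expand a pixels x bands reference line to the cube dimension
broadcast_frame <- function(frame, d, what) {
  if (is.matrix(frame)) {
    if (!all(dim(frame) == d[2:3]))
      stop(what, " must be pixels x bands (", d[2], " x ", d[3], ")")
    return(aperm(array(frame, dim = c(d[2], d[3], d[1])), c(3, 1, 2)))
  }
  if (!is.array(frame) || !all(dim(frame) == d))
    stop(what, " must match raw_cube dimensions or be pixels x bands")
  frame
}

#' Extract per-sample ROI mean spectra from a reflectance cube
#'
#' Each sample's spectrum is the arithmetic mean over all its region-of-
#' interest pixels at every band - the whole-dish ROI convention used for
#' bean samples.
#'
#' @param cube Reflectance array, lines x pixels x bands.
#' @param roi Integer label matrix (lines x pixels; 0 = background,
#'   k = pixels of sample k) or a list of logical mask matrices.
#' @param labels Class label per sample.
#' @param grid A [wavelength_grid()] for the band axis.
#' @param sample_ids Optional sample identifiers.
#' @return A [spectra_matrix()] with one row per sample, in sample order.
#' @export
extract_roi_spectra <- function(cube, roi, labels, grid,
                                sample_ids = NULL) {
  d <- dim(cube)
  if (length(d) != 3) stop("cube must be a 3-D array")
  grid <- as_wavelength_grid(grid)
  if (grid$n != d[3]) stop("grid length must equal the cube's band count")
  if (is.list(roi)) {
    masks <- lapply(roi, function(m) {
      if (!all(dim(m) == d[1:2]))
        stop("a mask overlaps the cube edge or has wrong dimensions")
      which(m)
    })
  } else {
    if (!all(dim(roi) == d[1:2]))
      stop("roi label matrix must be lines x pixels")
    n <- max(roi)
    masks <- lapply(seq_len(n), function(s) which(roi == s))
  }
  if (length(masks) != length(labels))
    stop("need one label per ROI")
  flat <- matrix(cube, nrow = d[1] * d[2])
  refl <- matrix(NA_real_, length(masks), d[3])
  for (s in seq_along(masks)) {
    if (length(masks[[s]]) == 0)
      stop("ROI mask ", s, " is empty")
    refl[s, ] <- colMeans(flat[masks[[s]], , drop = FALSE])
  }
  spectra_matrix(refl, grid, labels, sample_ids)
}

#' Trim a spectra matrix to a working wavelength window
#'
#' Keeps exactly the bands whose centers lie in the closed interval
#' `[lo_nm, hi_nm]`. Detector edges of NIR line-scan instruments are
#' low-signal and noisy, so analysis conventionally restricts to an
#' interior window (default 930-1700 nm).
#'
#' @param x A [spectra_matrix()].
#' @param lo_nm,hi_nm Window bounds in nm (both endpoints included).
#' @return A trimmed `spectra_matrix`.
#' @export
trim_bands <- function(x, lo_nm = 930, hi_nm = 1700) {
  stopifnot(inherits(x, "spectra_matrix"))
  if (lo_nm >= hi_nm) stop("lo_nm must be less than hi_nm")
  keep <- x$grid$centers >= lo_nm & x$grid$centers <= hi_nm
  if (!any(keep))
    stop("no bands fall inside [", lo_nm, ", ", hi_nm, "] nm")
  spectra_matrix(x$reflectance[, keep, drop = FALSE],
                 wavelength_grid(x$grid$centers[keep]),
                 x$labels, x$sample_ids)
}

#' Calibrate and extract a synthetic scene in one step
#'
#' Convenience wrapper: applies [calibrate_reflectance()] to a
#' [generate_scene()] result and extracts its ROI mean spectra.
#'
#' @param scene A `raw_scene`.
#' @return A [spectra_matrix()].
#' @export
calibrate_scene <- function(scene) {
  stopifnot(inherits(scene, "raw_scene"))
  R <- calibrate_reflectance(scene$raw_cube, scene$dark_frame,
                             scene$white_frame)
  extract_roi_spectra(R, scene$roi, scene$labels, scene$grid,
                      scene$sample_ids)
}
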