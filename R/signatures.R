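#' Class-dependent NIR reflectance signatures for roasting degrees
#'
#' Builds one smooth reflectance curve per roasting-degree class over a
#' wavelength grid. Every class shares a common baseline shape - rising
#' from ~930 nm, a small absorption valley near 1210 nm (second C-H
#' overtone, tracking crude fat), a shoulder near 1350 nm (-CH2
#' stretching), a deep water valley near 1450 nm (first O-H overtone) and
#' a weak feature near 1660 nm - while two ingredients separate the
#' classes: the depth of the 1210 nm valley deepens monotonically with
#' roasting degree, and a broad class-offset bump centered at 1140 nm
#' shifts overall reflectance within the 930-1350 nm window. Both
#' class-dependent terms live inside 930-1350 nm, so the largest pairwise
#' difference between any two class signatures falls in that window.
#'
#' @param grid A [wavelength_grid()].
#' @param n_classes Number of roasting-degree classes (>= 2, default 7).
#' @param features Data frame with columns `center`, `sigma`, `depth`
#'   describing the shared negative-Gaussian absorption features
#'   (nm, nm, reflectance units).
#' @param class_depth_step Per-class increment of the 1210 nm feature
#'   depth (reflectance units per class step).
#' @param class_offset_step Per-class vertical offset of the 1140 nm
#'   separation bump (reflectance units per class step).
#' @param seed Optional integer; only used when `depth_jitter_sd > 0`.
#' @param depth_jitter_sd SD of optional random jitter applied to the
#'   class-dependent 1210 nm depths (default 0: fully deterministic).
#' @return An object of class `class_signatures`: a list with the
#'   reflectance matrix (`n_classes` x bands), the grid, class labels in
#'   roasting order and the per-class 1210 nm feature depths.
#' @examples
#' sig <- make_class_signatures(wavelength_grid(), 7)
#' matplot(sig$grid$centers, t(sig$reflectance), type = "l")
#' @export
make_class_signatures <- function(grid = wavelength_grid(),
                                  n_classes = 7,
                                  features = default_features(),
                                  class_depth_step = 0.012,
                                  class_offset_step = 0.025,
                                  seed = NULL,
                                  depth_jitter_sd = 0) {
  grid <- as_wavelength_grid(grid)
  if (!is.numeric(n_classes) || n_classes < 2)
    stop("n_classes must be at least 2")
  n_classes <- as.integer(n_classes)
  stopifnot(is.data.frame(features),
            all(c("center", "sigma", "depth") %in% names(features)))

  wl <- grid$centers
  x <- (wl - min(wl)) / max(diff(range(wl)), 1)
  baseline <- 0.50 + 0.25 * x - 0.15 * x^2

  gauss <- function(center, sigma) exp(-(wl - center)^2 / (2 * sigma^2))
  shared <- rep(0, grid$n)
  for (f in seq_len(nrow(features)))
    shared <- shared + features$depth[f] *
      gauss(features$center[f], features$sigma[f])

  # class-dependent depth at the 1210 nm feature, monotone in roast order
  i1210 <- which.min(abs(features$center - 1210))
  depth1210 <- features$depth[i1210] +
    class_depth_step * (seq_len(n_classes) - 1)
  if (depth_jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    depth1210 <- depth1210 +
      stats::rnorm(n_classes, 0, depth_jitter_sd)
  }
  extra1210 <- depth1210 - features$depth[i1210]
  g1210 <- gauss(features$center[i1210], features$sigma[i1210])

  # broad separation bump, confined to the 930-1350 nm window;
  # darker roasts sit lower, so the bump offset decreases with class index
  bump <- gauss(1140, 140)
  offsets <- class_offset_step * ((n_classes + 1) / 2 - seq_len(n_classes))

  refl <- matrix(NA_real_, n_classes, grid$n)
  for (cls in seq_len(n_classes))
    refl[cls, ] <- baseline - shared - extra1210[cls] * g1210 +
      offsets[cls] * bump
  if (any(refl <= 0) || any(refl >= 1))
    stop("signature parameters push reflectance outside (0, 1); ",
         "reduce depths or offsets")

  structure(list(reflectance = refl, grid = grid, n_classes = n_classes,
                 labels = roast_labels(n_classes),
                 feature_1210_depth = depth1210,
                 baseline = baseline,
                 params = list(features = features,
                               class_depth_step = class_depth_step,
                               class_offset_step = class_offset_step)),
            class = "class_signatures")
}

#' Default shared absorption features
#'
#' Negative-Gaussian absorption features shared by all classes, placed at
#' the canonical NIR overtone positions for plant material: ~940 nm
#' (third C-H overtone), ~1210 nm (second C-H overtone, fat), ~1350 nm
#' (-CH2 stretch), ~1450 nm (first O-H overtone, water) and ~1660 nm
#' (first C-H overtone).
#'
#' @return Data frame with columns `center` (nm), `sigma` (nm), `depth`
#'   (reflectance units).
#' @export
default_features <- function() {
  data.frame(center = c(940, 1210, 1350, 1450, 1660),
             sigma  = c(25, 30, 45, 40, 30),
             depth  = c(0.03, 0.04, 0.06, 0.18, 0.03))
}

#' @export
print.class_signatures <- function(x, ...) {
  cat(sprintf("<class_signatures> %d classes over %d bands (%.0f-%.0f nm)\n",
              x$n_classes, x$grid$n, min(x$grid$centers), max(x$grid$centers)))
  invisible(x)
}
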