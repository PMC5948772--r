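#' Configuration of a synthetic hyperspectral scene
#'
#' Describes a simulated line-scan acquisition of coffee-bean samples.
#' Each *sample* is a dish of `beans_per_sample` beans; all beans of one
#' sample share its region of interest (ROI). The raw cube is generated
#' in digital-number (DN) space by inverting the reflectance-calibration
#' identity: `raw = dark + R * (white - dark) + noise`, with independent
#' Gaussian pixel noise whose SD (expressed in reflectance units) is
#' `noise_sd_interior` for bands inside `edge_bounds` and `noise_sd_edge`
#' for the noisy detector edges outside it. Sample-to-sample variability
#' is modelled as a multiplicative scatter factor `N(1, scatter_sd)` and
#' an additive offset `N(0, offset_sd)` applied to the class signature.
#'
#' @param n_classes Number of roasting-degree classes (default 7).
#' @param samples_per_class Samples per class (default 75, so 525 total).
#' @param beans_per_sample Beans per dish (default 30).
#' @param bean_height,bean_width Ellipse axes of one bean in pixels.
#' @param image_height,image_width Scene size in pixels; `NULL` sizes the
#'   image automatically to fit all samples.
#' @param noise_sd_interior Per-pixel noise SD in reflectance units for
#'   bands inside `edge_bounds`.
#' @param noise_sd_edge Noise SD outside `edge_bounds`; must be at least
#'   `noise_sd_interior` (edge bands are the noisy ones). Default 10x.
#' @param scatter_sd SD of the per-sample multiplicative scatter factor.
#' @param offset_sd SD of the per-sample additive reflectance offset.
#' @param edge_bounds Two wavelengths (nm) delimiting the low-noise
#'   interior of the spectral range.
#' @param dark_level,white_level Reference DN levels of the dark and
#'   white frames.
#' @param background_reflectance Reflectance of non-bean pixels.
#' @param seed Integer seed controlling all randomness.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(n_classes = 7, samples_per_class = 75,
                         beans_per_sample = 30,
                         bean_height = 6, bean_width = 9,
                         image_height = NULL, image_width = NULL,
                         noise_sd_interior = 0.01,
                         noise_sd_edge = 10 * noise_sd_interior,
                         scatter_sd = 0.01, offset_sd = 0.003,
                         edge_bounds = c(930, 1700),
                         dark_level = 100, white_level = 4000,
                         background_reflectance = 0.12,
                         seed = 1) {
  counts <- c(n_classes = n_classes, samples_per_class = samples_per_class,
              beans_per_sample = beans_per_sample,
              bean_height = bean_height, bean_width = bean_width)
  if (any(counts < 1)) stop("all counts must be positive")
  if (n_classes < 2) stop("need at least 2 classes")
  if (noise_sd_edge < noise_sd_interior)
    stop("noise_sd_edge must be >= noise_sd_interior")
  if (white_level <= dark_level)
    stop("white_level must exceed dark_level")
  stopifnot(length(edge_bounds) == 2, edge_bounds[1] < edge_bounds[2])
  structure(list(n_classes = as.integer(n_classes),
                 samples_per_class = as.integer(samples_per_class),
                 beans_per_sample = as.integer(beans_per_sample),
                 bean_height = as.integer(bean_height),
                 bean_width = as.integer(bean_width),
                 image_height = image_height, image_width = image_width,
                 noise_sd_interior = noise_sd_interior,
                 noise_sd_edge = noise_sd_edge,
                 scatter_sd = scatter_sd, offset_sd = offset_sd,
                 edge_bounds = edge_bounds,
                 dark_level = dark_level, white_level = white_level,
                 background_reflectance = background_reflectance,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# ellipse stamp for one bean (logical matrix bean_height x bean_width)
bean_stamp <- function(h, w) {
  r <- (row(matrix(0, h, w)) - (h + 1) / 2) / (h / 2)
  c <- (col(matrix(0, h, w)) - (w + 1) / 2) / (w / 2)
  r^2 + c^2 <= 1
}

# grid layout: returns list(roi = integer label matrix, height, width)
layout_masks <- function(config) {
  n <- config$n_classes * config$samples_per_class
  gap <- 2L
  bh <- config$bean_height; bw <- config$bean_width
  bcols <- ceiling(sqrt(config$beans_per_sample))
  brows <- ceiling(config$beans_per_sample / bcols)
  cell_h <- brows * (bh + gap) + gap
  cell_w <- bcols * (bw + gap) + gap
  scols <- ceiling(sqrt(n))
  srows <- ceiling(n / scols)
  need_h <- srows * cell_h
  need_w <- scols * cell_w
  H <- if (is.null(config$image_height)) need_h else config$image_height
  W <- if (is.null(config$image_width)) need_w else config$image_width
  if (H < need_h || W < need_w)
    stop(sprintf(paste0("image %dx%d too small to place %d samples of %d",
                        " disjoint beans (need at least %dx%d)"),
                 H, W, n, config$beans_per_sample, need_h, need_w))
  roi <- matrix(0L, H, W)
  stamp <- bean_stamp(bh, bw)
  for (s in seq_len(n)) {
    sr <- (s - 1) %/% scols
    sc <- (s - 1) %% scols
    for (b in seq_len(config$beans_per_sample)) {
      br <- (b - 1) %/% bcols
      bc <- (b - 1) %% bcols
      r0 <- sr * cell_h + gap + br * (bh + gap)
      c0 <- sc * cell_w + gap + bc * (bw + gap)
      block <- roi[r0 + seq_len(bh), c0 + seq_len(bw)]
      block[stamp] <- s
      roi[r0 + seq_len(bh), c0 + seq_len(bw)] <- block
    }
  }
  list(roi = roi, height = H, width = W)
}

# per-band noise SD in reflectance units (edge bands are noisier)
band_noise_sd <- function(config, grid) {
  inside <- grid$centers >= config$edge_bounds[1] &
    grid$centers <= config$edge_bounds[2]
  ifelse(inside, config$noise_sd_interior, config$noise_sd_edge)
}

# sample-level scatter/offset draws; shared (same RNG order) by both the
# scene path and the fast spectra path so the noiseless limits coincide
draw_sample_effects <- function(config) {
  n <- config$n_classes * config$samples_per_class
  list(scatter = stats::rnorm(n, 1, config$scatter_sd),
       offset = stats::rnorm(n, 0, config$offset_sd))
}

scene_labels <- function(config, signatures) {
  factor(rep(signatures$labels[seq_len(config$n_classes)],
             each = config$samples_per_class),
         levels = signatures$labels[seq_len(config$n_classes)])
}

#' Generate a synthetic raw hyperspectral scene
#'
#' Builds a raw digital-number cube of labelled bean samples together
#' with dark and white reference frames and an ROI label image, by
#' inverting the reflectance calibration: each bean pixel holds
#' `dark + R * (white - dark)` plus Gaussian noise, where `R` is the
#' sample's (scatter-perturbed) class signature. Reference frames are
#' stored as single-line frames (pixels x bands), matching the line-scan
#' acquisition geometry in which one reference line is broadcast along
#' the scan axis.
#'
#' @param config A [scene_config()].
#' @param signatures A [make_class_signatures()] object covering at least
#'   `config$n_classes` classes on the target grid.
#' @return An object of class `raw_scene`: `raw_cube` (lines x pixels x
#'   bands), `dark_frame` and `white_frame` (pixels x bands), `roi`
#'   (integer label matrix, 0 = background), `labels`, `sample_ids`,
#'   `grid` and `config`.
#' @export
generate_scene <- function(config, signatures) {
  stopifnot(inherits(config, "scene_config"),
            inherits(signatures, "class_signatures"))
  if (signatures$n_classes < config$n_classes)
    stop("signatures cover fewer classes than the scene requires")
  grid <- signatures$grid
  lay <- layout_masks(config)
  H <- lay$height; W <- lay$width; p <- grid$n
  n <- config$n_classes * config$samples_per_class

  set.seed(config$seed)
  eff <- draw_sample_effects(config)
  labels <- scene_labels(config, signatures)
  cls <- as.integer(labels)

  span <- config$white_level - config$dark_level
  refl <- matrix(config$background_reflectance, H * W, p)
  for (s in seq_len(n)) {
    idx <- which(lay$roi == s)
    sig <- eff$scatter[s] * signatures$reflectance[cls[s], ] + eff$offset[s]
    refl[idx, ] <- matrix(sig, length(idx), p, byrow = TRUE)
  }
  sd_band <- band_noise_sd(config, grid) * span
  noise <- matrix(stats::rnorm(H * W * p), H * W, p)
  noise <- sweep(noise, 2, sd_band, `*`)
  raw <- config$dark_level + refl * span + noise
  raw_cube <- array(raw, dim = c(H, W, p))

  structure(list(raw_cube = raw_cube,
                 dark_frame = matrix(config$dark_level, W, p),
                 white_frame = matrix(config$white_level, W, p),
                 roi = lay$roi,
                 labels = labels,
                 sample_ids = sprintf("S%04d", seq_len(n)),
                 grid = grid, config = config),
            class = "raw_scene")
}

#' @export
print.raw_scene <- function(x, ...) {
  d <- dim(x$raw_cube)
  cat(sprintf("<raw_scene> %d x %d px, %d bands, %d samples (%d classes)\n",
              d[1], d[2], d[3], length(x$labels), nlevels(x$labels)))
  invisible(x)
}

#' Generate a spectra matrix directly (fast path)
#'
#' Produces the same per-sample ROI-mean spectra that
#' [generate_scene()] followed by calibration and ROI extraction would
#' yield, without materialising the image. Per-band noise is scaled by
#' `1/sqrt(n_roi_pixels)` to reproduce the variance of an ROI mean over
#' independent pixel noise. In the noiseless limit the two paths agree
#' exactly (the sample-level scatter draws consume the RNG in the same
#' order).
#'
#' @inheritParams generate_scene
#' @return A [spectra_matrix()] with `n_classes * samples_per_class` rows.
#' @examples
#' sig <- make_class_signatures()
#' sm <- generate_spectra_matrix(scene_config(samples_per_class = 3), sig)
#' dim(sm)
#' @export
generate_spectra_matrix <- function(config, signatures) {
  stopifnot(inherits(config, "scene_config"),
            inherits(signatures, "class_signatures"))
  if (signatures$n_classes < config$n_classes)
    stop("signatures cover fewer classes than the configuration requires")
  grid <- signatures$grid
  n <- config$n_classes * config$samples_per_class
  p <- grid$n

  set.seed(config$seed)
  eff <- draw_sample_effects(config)
  labels <- scene_labels(config, signatures)
  cls <- as.integer(labels)

  n_roi <- config$beans_per_sample *
    sum(bean_stamp(config$bean_height, config$bean_width))
  sd_band <- band_noise_sd(config, grid) / sqrt(n_roi)

  refl <- matrix(NA_real_, n, p)
  for (s in seq_len(n))
    refl[s, ] <- eff$scatter[s] * signatures$reflectance[cls[s], ] +
      eff$offset[s] + stats::rnorm(p, 0, 1) * sd_band
  spectra_matrix(refl, grid, labels)
}
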