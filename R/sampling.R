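#' Kennard-Stone calibration/prediction split
#'
#' Deterministic max-min-distance partitioning of samples into a
#' representative calibration set and a prediction set. The calibration
#' set is seeded with the two samples at maximal pairwise Euclidean
#' distance in spectral space; samples are then added one at a time,
#' always choosing the sample whose minimum distance to the current
#' calibration set is largest, until `round(cal_fraction * n)` samples
#' are selected. Ties are broken by the lowest row index, making the
#' procedure fully reproducible.
#'
#' @param x A [spectra_matrix()] or a numeric matrix (rows = samples).
#' @param cal_fraction Target calibration fraction in (0, 1); the
#'   default 2/3 gives the conventional 2:1 split (e.g. 350/175 out of
#'   525).
#' @param per_class Logical; if `TRUE` and `x` carries labels, the split
#'   is run independently within each class (the global split is the
#'   default).
#' @return An object of class `ks_split`: `calibration` (indices in
#'   selection order), `prediction` (ascending), `ratio`, and
#'   `selection_distances` (the max-min distance at which each
#'   calibration sample after the seed pair was admitted).
#' @examples
#' X <- matrix(c(0, 1, 10), ncol = 1)
#' kennard_stone_split(X, 2 / 3)$calibration
#' @export
kennard_stone_split <- function(x, cal_fraction = 2 / 3,
                                per_class = FALSE) {
  X <- if (inherits(x, "spectra_matrix")) x$reflectance else as.matrix(x)
  n <- nrow(X)
  if (!is.numeric(cal_fraction) || cal_fraction <= 0 || cal_fraction >= 1)
    stop("cal_fraction must lie strictly between 0 and 1")
  if (per_class) {
    if (!inherits(x, "spectra_matrix"))
      stop("per-class splitting needs a spectra_matrix with labels")
    idx_by_class <- split(seq_len(n), x$labels)
    parts <- lapply(idx_by_class, function(idx)
      ks_core(X[idx, , drop = FALSE], cal_fraction, idx))
    cal <- unlist(lapply(parts, `[[`, "calibration"), use.names = FALSE)
    dists <- unlist(lapply(parts, `[[`, "distances"), use.names = FALSE)
  } else {
    part <- ks_core(X, cal_fraction, seq_len(n))
    cal <- part$calibration
    dists <- part$distances
  }
  structure(list(calibration = cal,
                 prediction = sort(setdiff(seq_len(n), cal)),
                 ratio = cal_fraction,
                 selection_distances = dists),
            class = "ks_split")
}

ks_core <- function(X, cal_fraction, orig_idx) {
  n <- nrow(X)
  if (n < 3) stop("Kennard-Stone needs at least 3 samples")
  n_cal <- round(cal_fraction * n)
  if (n_cal < 2 || n_cal >= n)
    stop("cal_fraction leaves fewer than 2 calibration or 1 prediction sample")
  D <- as.matrix(stats::dist(X))
  # seed pair: maximal distance, ties broken lexicographically by index
  hits <- which(D == max(D), arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  sel <- c(hits[1, 1], hits[1, 2])
  in_cal <- logical(n)
  in_cal[sel] <- TRUE
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  dists <- numeric(0)
  while (length(sel) < n_cal) {
    cand <- which(!in_cal)
    nxt <- cand[which.max(mind[cand])]   # which.max: lowest index on ties
    dists <- c(dists, mind[nxt])
    sel <- c(sel, nxt)
    in_cal[nxt] <- TRUE
    mind <- pmin(mind, D[, nxt])
  }
  list(calibration = orig_idx[sel], distances = dists)
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("<ks_split> %d calibration / %d prediction (ratio %.3f)\n",
              length(x$calibration), length(x$prediction), x$ratio))
  invisible(x)
}

#' Write a split assignment as CSV
#'
#' @param split A `ks_split`.
#' @param sample_ids Character ids, one per original row.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_split_csv <- function(split, sample_ids, path) {
  n <- length(split$calibration) + length(split$prediction)
  subset <- rep("prediction", n)
  subset[split$calibration] <- "calibration"
  utils::write.csv(data.frame(sample_id = sample_ids, subset = subset),
                   path, row.names = FALSE)
  invisible(path)
}
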