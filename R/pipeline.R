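#' Build a validated end-to-end run configuration
#'
#' Collects every stage's parameters into one list: scene generation,
#' band trimming, Kennard-Stone partitioning, wavelength selection and
#' LS-SVM modelling. Two profiles are provided: `"test"` (default)
#' downscales the stochastic selector (`T = 1000`, `n_runs = 5`) and
#' the gamma grid (20 points) so a full run stays light; `"full"` uses
#' the conventional full-scale settings (`T = 10000`, `n_runs = 50`,
#' 100 grid points).
#'
#' @param profile `"test"` or `"full"`.
#' @param scene A [scene_config()].
#' @param use_image Logical; `TRUE` runs the image path (scene ->
#'   ENVI -> calibrate -> extract), `FALSE` the fast spectra path.
#' @param trim_window Two wavelengths (nm) for [trim_bands()].
#' @param cal_fraction Kennard-Stone calibration fraction.
#' @param selector `"rf"`, `"spa"`, `"xloading"` or `"none"` (train on
#'   all trimmed bands).
#' @param n_select Number of effective wavelengths to keep (defaults:
#'   8 for rf, 5 for spa, 7 for xloading).
#' @param rf An [rf_params()]; `NULL` takes the profile default.
#' @param lssvm An [lssvm_params()]; `NULL` takes the profile default.
#' @param seed Master seed propagated to all stochastic stages.
#' @param out_dir Output directory for run artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(profile = c("test", "full"),
                       scene = scene_config(seed = seed),
                       use_image = FALSE,
                       trim_window = c(930, 1700),
                       cal_fraction = 2 / 3,
                       selector = c("rf", "spa", "xloading", "none"),
                       n_select = NULL,
                       rf = NULL, lssvm = NULL,
                       seed = 1, out_dir = tempfile("roastspec_run_")) {
  profile <- match.arg(profile)
  selector <- match.arg(selector)
  if (is.null(n_select))
    n_select <- switch(selector, rf = 8, spa = 5, xloading = 7, none = NA)
  if (is.null(rf))
    rf <- if (profile == "test")
      rf_params(T = 1000, n_runs = 5, seed = seed)
    else rf_params(seed = seed)
  if (is.null(lssvm))
    lssvm <- if (profile == "test")
      lssvm_params(gamma_grid = 10^seq(0, 3, length.out = 20), seed = seed)
    else lssvm_params(seed = seed)
  cfg <- structure(list(profile = profile, scene = scene,
                        use_image = use_image,
                        trim_window = trim_window,
                        cal_fraction = cal_fraction,
                        selector = selector, n_select = n_select,
                        rf = rf, lssvm = lssvm,
                        seed = as.integer(seed), out_dir = out_dir),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"),
            inherits(cfg$scene, "scene_config"),
            inherits(cfg$rf, "rf_params"),
            inherits(cfg$lssvm, "lssvm_params"),
            is.logical(cfg$use_image),
            length(cfg$trim_window) == 2,
            cfg$trim_window[1] < cfg$trim_window[2],
            cfg$cal_fraction > 0, cfg$cal_fraction < 1,
            cfg$selector %in% c("rf", "spa", "xloading", "none"))
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Recognised top-level keys mirror the arguments of [run_config()];
#' `scene`, `rf` and `lssvm` may be nested maps of the corresponding
#' constructor arguments. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("profile", "scene", "use_image", "trim_window",
             "cal_fraction", "selector", "n_select", "rf", "lssvm",
             "seed", "out_dir")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- raw
  seed <- if (is.null(raw$seed)) 1 else raw$seed
  if (!is.null(raw$scene)) args$scene <- do.call(scene_config,
                                                 c(raw$scene, list(seed = seed)))
  if (!is.null(raw$rf)) args$rf <- do.call(rf_params, raw$rf)
  if (!is.null(raw$lssvm)) args$lssvm <- do.call(lssvm_params, raw$lssvm)
  if (!is.null(raw$trim_window)) args$trim_window <- unlist(raw$trim_window)
  do.call(run_config, args)
}

#' Run the full classification pipeline
#'
#' Sequences simulate (or ingest) -> calibrate -> extract -> trim ->
#' Kennard-Stone split -> wavelength selection -> gamma tuning ->
#' multiclass LS-SVM training -> evaluation, writing every intermediate
#' artifact (CSV/JSON, plus an ENVI cube on the image path) into
#' `config$out_dir` together with a deterministic manifest (config,
#' seeds, package version and per-artifact MD5 checksums). Selection
#' and tuning use calibration rows only; accuracy is reported on the
#' held-out prediction rows, alongside a stratified 10-fold
#' cross-validated accuracy within the calibration set.
#'
#' @param config A [run_config()].
#' @param spectra Optional pre-built [spectra_matrix()]; skips the
#'   simulation stage (for user-supplied data).
#' @return Invisibly, a list with `manifest`, the fitted model, the
#'   `selection_result`, the prediction-set `confusion_matrix` and the
#'   accuracy metrics.
#' @export
run_pipeline <- function(config, spectra = NULL) {
  validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- character(0)
  put <- function(name) file.path(config$out_dir, name)

  # --- simulate / ingest ---------------------------------------------
  if (is.null(spectra)) {
    signatures <- make_class_signatures(n_classes = config$scene$n_classes)
    if (config$use_image) {
      scene <- generate_scene(config$scene, signatures)
      write_scene(scene, put("scene"))
      art <- c(art, file.path("scene", c("raw.bil", "raw.hdr",
                                         "roi.csv", "labels.csv")))
      spectra <- calibrate_scene(scene)
    } else {
      spectra <- generate_spectra_matrix(config$scene, signatures)
    }
  }
  write_spectra_csv(spectra, put("spectra.csv"))
  art <- c(art, "spectra.csv")

  # --- trim + split --------------------------------------------------
  trimmed <- trim_bands(spectra, config$trim_window[1],
                        config$trim_window[2])
  split <- kennard_stone_split(trimmed, config$cal_fraction)
  write_split_csv(split, trimmed$sample_ids, put("split.csv"))
  art <- c(art, "split.csv")
  cal <- trimmed[split$calibration]
  pred <- trimmed[split$prediction]

  # --- wavelength selection (calibration rows only) ------------------
  if (config$selector == "none") {
    band_idx <- seq_len(trimmed$grid$n)
    selection <- NULL
  } else {
    y_cal <- class_response(cal$labels)
    selection <- switch(config$selector,
      xloading = xloading_select(pca_fit(cal, k = 2),
                                 n_select = config$n_select),
      spa = spa_select(cal, y_cal, n_select = config$n_select),
      rf = random_frog(cal, y_cal, config$rf,
                       n_select = config$n_select))
    write_selection_csv(selection, put("selection.csv"))
    art <- c(art, "selection.csv")
    band_idx <- sort(selection$selected_indices)
  }
  Xcal <- cal$reflectance[, band_idx, drop = FALSE]
  Xpred <- pred$reflectance[, band_idx, drop = FALSE]

  # --- tune + train + evaluate ---------------------------------------
  # folds cannot exceed the smallest class count in the calibration set
  lpar <- config$lssvm
  lpar$cv_folds <- min(lpar$cv_folds,
                       as.integer(min(table(cal$labels))))
  tuned <- tune_lssvm(Xcal, cal$labels, lpar)
  model <- lssvm_train_multiclass(Xcal, cal$labels, tuned)
  predicted <- predict(model, Xpred)
  utils::write.csv(data.frame(sample_id = pred$sample_ids,
                              truth = as.character(pred$labels),
                              predicted = as.character(predicted)),
                   put("predictions.csv"), row.names = FALSE)
  art <- c(art, "predictions.csv")

  class_order <- levels(trimmed$labels)
  cm <- confusion(pred$labels, predicted, class_order)
  write_confusion_csv(cm, put("confusion.csv"))
  cv_acc <- lssvm_cross_validate(Xcal, cal$labels, tuned)
  metrics <- list(prediction_accuracy = overall_accuracy(cm),
                  misclassified = misclassified_count(cm),
                  cv_accuracy = cv_acc,
                  gamma = tuned$gamma, sigma2 = tuned$sigma2,
                  n_bands = length(band_idx))
  jsonlite::write_json(metrics, put("metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  art <- c(art, "confusion.csv", "metrics.json")

  manifest <- list(
    package_version = as.character(utils::packageVersion("roastspec")),
    seed = config$seed,
    profile = config$profile,
    selector = config$selector,
    n_bands = length(band_idx),
    selected_wavelengths = if (is.null(selection)) numeric(0)
                           else selection$selected_wavelengths,
    metrics = metrics,
    config_hash = config_hash(config),
    checksums = as.list(tools::md5sum(file.path(config$out_dir, art))))
  names(manifest$checksums) <- art
  jsonlite::write_json(manifest, put("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(manifest = manifest, model = model,
                 selection = selection, confusion = cm,
                 metrics = metrics, split = split, spectra = trimmed))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  cfg <- config
  cfg$out_dir <- NULL
  saveRDS(cfg, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}
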