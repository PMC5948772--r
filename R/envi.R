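#' Write a hypercube as an ENVI band-interleaved-by-line (BIL) file
#'
#' Writes `<prefix>.bil` (binary, little-endian) and a plain-text
#' `<prefix>.hdr` in the ENVI header dialect (`samples`, `lines`,
#' `bands`, `interleave = bil`, `wavelength = {...}`). BIL order stores,
#' for each scan line, one row of samples per band. Data are written as
#' 64-bit floats (ENVI data type 5) by default for lossless round trips;
#' 32-bit floats (type 4) are also supported.
#'
#' @param values 3-D numeric array, lines x pixels(samples) x bands.
#' @param grid A [wavelength_grid()] matching the band axis.
#' @param prefix Path prefix (without extension).
#' @param data_type ENVI data type code: 4 (float32) or 5 (float64).
#' @return `write_envi_cube` returns `prefix` invisibly;
#'   `read_envi_cube` returns `list(values, grid)`.
#' @export
write_envi_cube <- function(values, grid, prefix, data_type = 5) {
  d <- dim(values)
  if (length(d) != 3) stop("values must be a 3-D array")
  grid <- as_wavelength_grid(grid)
  if (grid$n != d[3]) stop("grid length must equal the band count")
  if (!data_type %in% c(4, 5)) stop("data_type must be 4 or 5")
  size <- if (data_type == 4) 4L else 8L

  hdr <- c("ENVI",
           "description = {synthetic hyperspectral cube}",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           sprintf("data type = %d", data_type),
           "interleave = bil",
           "byte order = 0",
           "wavelength units = Nanometers",
           paste0("wavelength = {",
                  paste(sprintf("%.6f", grid$centers), collapse = ", "),
                  "}"))
  writeLines(hdr, paste0(prefix, ".hdr"))

  # BIL: for each line, band-major rows of samples
  perm <- aperm(values, c(2, 3, 1))   # samples x bands x lines
  con <- file(paste0(prefix, ".bil"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(perm), con, size = size, endian = "little")
  invisible(prefix)
}

#' @rdname write_envi_cube
#' @export
read_envi_cube <- function(prefix) {
  hdr_path <- paste0(prefix, ".hdr")
  if (!file.exists(hdr_path)) stop("missing header file: ", hdr_path)
  lines <- readLines(hdr_path, warn = FALSE)
  text <- paste(lines, collapse = "\n")

  get_num <- function(key) {
    m <- regmatches(text, regexpr(sprintf("%s\\s*=\\s*([0-9]+)", key), text))
    if (!length(m)) stop("header lacks '", key, "'")
    as.integer(sub(sprintf("%s\\s*=\\s*", key), "", m))
  }
  ns <- get_num("samples"); nl <- get_num("lines"); nb <- get_num("bands")
  dt <- get_num("data type")
  if (!dt %in% c(4, 5)) stop("unsupported ENVI data type: ", dt)
  il <- regmatches(text, regexpr("interleave\\s*=\\s*\\w+", text))
  if (!length(il) || !grepl("bil", il, ignore.case = TRUE))
    stop("only BIL interleave is supported")
  wl_m <- regmatches(text, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", text))
  if (!length(wl_m)) stop("header lacks a wavelength block")
  inner <- sub(".*\\{", "", sub("\\}.*", "", wl_m))
  wl <- as.numeric(trimws(strsplit(inner, ",")[[1]]))
  if (length(wl) != nb) stop("wavelength list length differs from bands")

  size <- if (dt == 4) 4L else 8L
  con <- file(paste0(prefix, ".bil"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = ns * nl * nb, size = size,
                 endian = "little")
  if (length(raw) != ns * nl * nb) stop("BIL file shorter than expected")
  values <- aperm(array(raw, dim = c(ns, nb, nl)), c(3, 1, 2))
  list(values = values, grid = wavelength_grid(wl))
}

#' Write a raw scene to disk (ENVI cube plus sidecar text files)
#'
#' Writes the raw cube, the dark and white reference lines (as 1-line
#' ENVI cubes), the ROI label image as CSV and the sample labels as CSV.
#'
#' @param scene A `raw_scene`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "raw_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_envi_cube(scene$raw_cube, scene$grid, file.path(dir, "raw"))
  ref_dim <- c(1, dim(scene$dark_frame))
  write_envi_cube(array(scene$dark_frame, ref_dim), scene$grid,
                  file.path(dir, "dark"))
  write_envi_cube(array(scene$white_frame, ref_dim), scene$grid,
                  file.path(dir, "white"))
  utils::write.table(scene$roi, file.path(dir, "roi.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(data.frame(sample_id = scene$sample_ids,
                              label = as.character(scene$labels)),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  raw <- read_envi_cube(file.path(dir, "raw"))
  dark <- read_envi_cube(file.path(dir, "dark"))
  white <- read_envi_cube(file.path(dir, "white"))
  roi <- as.matrix(utils::read.csv(file.path(dir, "roi.csv"),
                                   header = FALSE))
  dimnames(roi) <- NULL
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  structure(list(raw_cube = raw$values,
                 dark_frame = dark$values[1, , ],
                 white_frame = white$values[1, , ],
                 roi = roi,
                 labels = factor(lab$label, levels = unique(lab$label)),
                 sample_ids = lab$sample_id,
                 grid = raw$grid, config = NULL),
            class = "raw_scene")
}
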