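#' Read an 8-bit grayscale image
#'
#' Supports single-channel TIFF and PNG; multi-channel images are reduced
#' to their first channel.
#'
#' @param path image path.
#' @return integer matrix with values in 0..255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) refp_stop("io_error", "image not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                refp_stop("invalid_argument", "unsupported image format: %s",
                          ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow = nrow(img))
}

#' Write an 8-bit grayscale image
#'
#' @param image integer/numeric matrix in 0..255.
#' @param path output path; format chosen by extension (.tif/.tiff/.png).
#' @return the path, invisibly.
#' @export
write_image <- function(image, path) {
  v <- clamp(image, 0, 255) / 255
  ext <- tolower(tools::file_ext(path))
  ok <- switch(ext,
               tif = , tiff = tiff::writeTIFF(v, path, bits.per.sample = 8L),
               png = { png::writePNG(v, path); TRUE },
               refp_stop("invalid_argument", "unsupported image format: %s",
                         ext))
  if (identical(ok, FALSE)) refp_stop("io_error", "failed to write %s", path)
  invisible(path)
}

#' Load and validate a dataset manifest
#'
#' A manifest is a CSV (or JSON array) with columns experiment, exposure_ms,
#' fov, z_um, path and optionally true_dz_um. The (experiment, exposure_ms,
#' fov, z_um) key must be unique, and image paths must resolve relative to
#' `image_dir`.
#'
#' @param path manifest file.
#' @param image_dir directory image paths are relative to; defaults to the
#'   manifest's directory.
#' @param check_paths verify that every image file exists.
#' @return the manifest data.frame, Z-sorted within each combination, with
#'   attribute `image_dir`.
#' @export
load_manifest <- function(path, image_dir = NULL, check_paths = TRUE) {
  if (!file.exists(path)) refp_stop("io_error", "manifest not found: %s", path)
  image_dir <- image_dir %||% dirname(path)
  ext <- tolower(tools::file_ext(path))
  m <- tryCatch(
    if (ext == "json") as.data.frame(jsonlite::read_json(path,
                                                         simplifyVector = TRUE))
    else read.csv(path, stringsAsFactors = FALSE),
    error = function(e) refp_stop("validation_error",
                                  "cannot parse manifest: %s",
                                  conditionMessage(e)))
  required <- c("experiment", "exposure_ms", "fov", "z_um", "path")
  missing <- setdiff(required, names(m))
  if (length(missing))
    refp_stop("validation_error", "manifest is missing column(s): %s",
              paste(missing, collapse = ", "))
  if (nrow(m) == 0) refp_stop("validation_error", "manifest is empty")
  keys <- paste(m$experiment, m$exposure_ms, m$fov, m$z_um, sep = "|")
  dup <- which(duplicated(keys))
  if (length(dup))
    refp_stop("validation_error",
              "duplicate (experiment, exposure, fov, z) at manifest row %d",
              dup[1])
  if (check_paths) {
    ok <- file.exists(file.path(image_dir, m$path))
    if (!all(ok))
      refp_stop("validation_error", "image not found for manifest row %d: %s",
                which(!ok)[1], m$path[which(!ok)[1]])
  }
  m <- m[order(m$experiment, m$exposure_ms, m$fov, m$z_um), , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "image_dir") <- image_dir
  class(m) <- c("dataset_manifest", "data.frame")
  m
}

#' Serialize a pooled profile (spline knots/coefficients and per-curve
#' alignment parameters) to JSON
#'
#' @param pooled list of `pooled_profile`s (one per feature) as attached to
#'   [estimate_refp()] output.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_pooled_json <- function(pooled, path) {
  ser <- lapply(pooled, function(p) list(
    feature = p$feature, reference_key = p$reference_key,
    range = p$range,
    spline = list(knot = p$fit$fit$knot, coef = p$fit$fit$coef,
                  min = p$fit$fit$min, range = p$fit$fit$range),
    alignments = p$alignments))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
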