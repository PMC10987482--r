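#' Threshold the darkest pixels of a field-of-view image
#'
#' Marks every pixel at or below the `pct`-th percentile of the image
#' intensities (linear-interpolation percentile) and groups marked pixels
#' into 8-connected clusters. Beads appear as dark objects in brightfield
#' images, so their bodies fall in the lowest percentile; on a degenerate
#' constant image the mask covers everything and downstream filters reject
#' the single resulting cluster.
#'
#' @param image single-channel numeric/integer matrix.
#' @param pct percentile in percent (default 1).
#' @return an object of class `bead_clusters`: list with `labels` (integer
#'   matrix, 0 = background), `n_clusters`, and `threshold`.
#' @export
threshold_percentile <- function(image, pct = 1) {
  if (!is.matrix(image) || length(image) == 0)
    refp_stop("invalid_argument", "image must be a non-empty matrix")
  thr <- as.numeric(quantile(image, pct / 100, type = 7, names = FALSE))
  mask <- image <= thr
  labels <- .label_components_cpp(mask)
  structure(list(labels = labels, n_clusters = attr(labels, "n_labels"),
                 threshold = thr, pct = pct),
            class = "bead_clusters")
}

#' Apply bead acceptance filters to thresholded clusters
#'
#' Applies, in order: (a) area >= `min_area` px; (b) circularity
#' `4*pi*area / perimeter^2` >= `min_circularity`, with the perimeter
#' estimated from the traced outer contour (chain length with corrected
#' weights, so rasterized disks score ~1); (c) contrast: on a sub-image of
#' the cluster bounding box dilated by one bead diameter, sd/mean of pixel
#' intensities must exceed `min_contrast` (eliminates dark background
#' shadows). The first failing filter is recorded per rejected cluster.
#'
#' @param clusters a `bead_clusters` object from [threshold_percentile()].
#' @param image the image the clusters came from.
#' @param min_area minimum cluster area in px.
#' @param min_circularity circularity acceptance threshold.
#' @param min_contrast minimum sd/mean on the dilated sub-image.
#' @param bead_diameter_px dilation amount for the contrast sub-image.
#' @return data.frame with one row per cluster: x, y (centroid, 0-based),
#'   area, perimeter, circularity, contrast, accepted, reject_reason.
#' @export
filter_clusters <- function(clusters, image, min_area = 180,
                            min_circularity = 0.9, min_contrast = 0.1,
                            bead_diameter_px = 19) {
  stopifnot(inherits(clusters, "bead_clusters"))
  n <- clusters$n_clusters
  if (n == 0)
    return(data.frame(x = numeric(0), y = numeric(0), area = numeric(0),
                      perimeter = numeric(0), circularity = numeric(0),
                      contrast = numeric(0), accepted = logical(0),
                      reject_reason = character(0)))
  # clusters far below the size threshold are rejected by area alone; skip
  # the boundary trace and hole fill for them
  st <- .cluster_stats_cpp(clusters$labels, n, min_area / 2)
  circ <- 4 * pi * st$area / st$perimeter^2
  reason <- rep(NA_character_, n)
  reason[st$area < min_area] <- "size"
  sel <- is.na(reason) & circ < min_circularity
  reason[sel] <- "circularity"
  # contrast is only consulted for clusters that survive the shape filters
  # (the filters are conjunctive, so this cannot change the accepted set)
  contrast <- rep(NA_real_, n)
  d <- ceiling(bead_diameter_px)
  for (k in which(is.na(reason))) {
    i0 <- max(1, st$ymin[k] + 1 - d); i1 <- min(nrow(image), st$ymax[k] + 1 + d)
    j0 <- max(1, st$xmin[k] + 1 - d); j1 <- min(ncol(image), st$xmax[k] + 1 + d)
    sub <- image[i0:i1, j0:j1]
    m <- mean(sub)
    contrast[k] <- if (m > 0) sd(sub) / m else 0
  }
  sel <- is.na(reason) & !is.na(contrast) & contrast <= min_contrast
  reason[sel] <- "contrast"
  data.frame(x = st$x, y = st$y, area = st$area, perimeter = st$perimeter,
             circularity = circ, contrast = contrast,
             accepted = is.na(reason), reject_reason = reason)
}

#' Detect beads in a field-of-view image
#'
#' Convenience wrapper: [threshold_percentile()] followed by
#' [filter_clusters()].
#'
#' @inheritParams threshold_percentile
#' @inheritParams filter_clusters
#' @param ... passed to [filter_clusters()].
#' @return the detections data.frame (accepted and rejected clusters).
#' @export
detect_beads <- function(image, pct = 1, ...) {
  cl <- threshold_percentile(image, pct)
  filter_clusters(cl, image, ...)
}

#' Crop a square tile around a detected bead
#'
#' The tile is centered on the rounded centroid; when the crop window would
#' exceed the image boundary it is shifted inward, so the bead may sit off
#' the tile center. The bead's nominal center in tile coordinates and the
#' number of saturated pixels are recorded.
#'
#' @param image source image matrix.
#' @param centroid continuous bead center `c(x, y)`, 0-based image
#'   coordinates.
#' @param tile_size tile side, typically 64 or 128 px.
#' @param key optional list identifying the source acquisition
#'   (experiment, exposure_ms, fov, z_um).
#' @param bead_id optional identifier.
#' @param saturation_level pixel value treated as saturated (default 255).
#' @return an object of class `bead_tile`: list with `pixels`,
#'   `nominal_center` (0-based tile coordinates), `offset` (tile origin in
#'   image coordinates), `saturated_count`, `key`, `bead_id`.
#' @export
crop_tile <- function(image, centroid, tile_size = 64, key = NULL,
                      bead_id = NA_integer_, saturation_level = 255) {
  nr <- nrow(image); nc <- ncol(image)
  if (tile_size > nr || tile_size > nc)
    refp_stop("invalid_argument", "tile_size larger than image")
  if (centroid[1] < 0 || centroid[1] > nc - 1 ||
      centroid[2] < 0 || centroid[2] > nr - 1)
    refp_stop("invalid_argument", "centroid outside image")
  x0 <- clamp(round(centroid[1]) - tile_size %/% 2, 0, nc - tile_size)
  y0 <- clamp(round(centroid[2]) - tile_size %/% 2, 0, nr - tile_size)
  px <- image[y0 + seq_len(tile_size), x0 + seq_len(tile_size)]
  structure(list(
    pixels = px,
    nominal_center = c(x = centroid[1] - x0, y = centroid[2] - y0),
    offset = c(x = x0, y = y0),
    saturated_count = sum(px >= saturation_level),
    key = key, bead_id = bead_id
  ), class = "bead_tile")
}

#' @export
print.bead_tile <- function(x, ...) {
  cat(sprintf("<bead_tile> %dx%d, center (%.2f, %.2f), %d saturated px\n",
              nrow(x$pixels), ncol(x$pixels), x$nominal_center[1],
              x$nominal_center[2], x$saturated_count))
  invisible(x)
}
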