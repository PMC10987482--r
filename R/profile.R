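#' Radial (distance, intensity) scatter of a tile about a candidate center
#' @noRd
radial_scatter <- function(pixels, center, max_radius) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  x <- rep(0:(nc - 1), each = nr)
  y <- rep(0:(nr - 1), times = nc)
  r <- sqrt((x - center[1])^2 + (y - center[2])^2)
  keep <- r <= max_radius
  list(r = r[keep], intensity = as.numeric(pixels)[keep])
}

#' Fit the radial-profile smoothing spline for a candidate bead center
#'
#' Builds the scatter of pixel intensity versus distance from `center` for
#' every tile pixel within `max_radius`, and fits a cubic smoothing spline
#' (penalized cubic B-spline with an integrated-squared-curvature penalty;
#' smoothing chosen by generalized cross-validation unless `lambda` is
#' given). The sum of squared residuals of this fit is the quantity
#' minimized during bead-center optimization: it is smallest when the
#' candidate center makes the bead's intensity most nearly a function of
#' radius alone.
#'
#' @param tile a `bead_tile` or plain intensity matrix.
#' @param center candidate center `c(x, y)`, 0-based tile coordinates.
#' @param max_radius include pixels up to this distance (px) from center.
#' @param dk knot spacing of the spline basis (px).
#' @param lambda smoothing parameter; `NULL` selects it by GCV.
#' @return an object of class `profile_fit` with the scatter, spline
#'   coefficients, `sse`, effective degrees of freedom and `lambda`.
#' @export
profile_sse <- function(tile, center = NULL, max_radius = 46, dk = 1.5,
                        lambda = NULL) {
  px <- tile_pixels(tile)
  if (is.null(center)) {
    center <- if (inherits(tile, "bead_tile")) tile$nominal_center
    else c(ncol(px), nrow(px)) / 2
  }
  if (center[1] < 0 || center[1] > ncol(px) - 1 ||
      center[2] < 0 || center[2] > nrow(px) - 1)
    refp_stop("invalid_argument", "center outside tile")
  sc <- radial_scatter(px, center, max_radius)
  xmax <- max(sc$r)
  if (xmax <= 0) refp_stop("fit_failure", "degenerate scatter")
  # fit on mean-normalized intensities so the GCV smoothing choice depends
  # only on the profile shape, never on the exposure scale; rescale after
  ym <- mean(sc$intensity)
  ys <- if (ym > 0) ym else 1
  fit <- tryCatch(
    .pspline_fit_cpp(sc$r, sc$intensity / ys, xmax, dk, lambda %||% -1),
    error = function(e) refp_stop("fit_failure", "spline fit failed: %s",
                                  conditionMessage(e)))
  structure(list(center = center, r = sc$r, intensity = sc$intensity,
                 coef = fit$coef * ys, xmax = fit$xmax, dk = fit$dk,
                 n = fit$n, sse = fit$sse * ys^2, edf = fit$edf,
                 lambda = fit$lambda,
                 saturated_count = if (inherits(tile, "bead_tile"))
                   tile$saturated_count else sum(px >= 255)),
            class = "profile_fit")
}

#' Evaluate a fitted radial profile spline
#'
#' @param object a `profile_fit`.
#' @param x distances (px) at which to evaluate.
#' @param deriv 0, 1 or 2.
#' @param ... unused.
#' @return numeric vector of spline (derivative) values.
#' @export
predict.profile_fit <- function(object, x, deriv = 0, ...) {
  as.numeric(.pspline_eval_cpp(object$coef, object$xmax, object$dk,
                               pmin(pmax(x, 0), object$xmax), deriv))
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf(
    "<profile_fit> center (%.2f, %.2f), n = %d, sse = %.4g, edf = %.1f\n",
    x$center[1], x$center[2], x$n, x$sse, x$edf))
  invisible(x)
}

#' Center-optimization objective: mean squared spline residual
#'
#' Mean squared residual of a fixed-smoothing cubic spline fit to the
#' radial scatter within `opt_radius` of the candidate center. The mean
#' (rather than the sum) is used because the number of scatter pixels
#' changes as the candidate center approaches a tile edge.
#'
#' @inheritParams profile_sse
#' @param opt_radius scatter radius (px) used during optimization.
#' @param lambda fixed smoothing parameter (required; pick it once by GCV at
#'   the initial center, see [optimize_center()]).
#' @export
center_objective <- function(tile, center, opt_radius = 14, dk = 1,
                             lambda) {
  .profile_mse_cpp(tile_pixels(tile), center[1], center[2], opt_radius, dk,
                   lambda)
}

#' Optimize the continuous bead center location
#'
#' Minimizes [center_objective()] over continuous (x, y) with a
#' derivative-free simplex search started at `initial_center` (the detection
#' centroid, or the tile midpoint). The smoothing parameter is selected by
#' GCV once at the initial center and then held fixed so that the objective
#' surface does not move under the optimizer.
#'
#' @inheritParams center_objective
#' @param initial_center starting center; defaults to the tile's nominal
#'   center (tile midpoint for plain matrices).
#' @param bounds maximum allowed displacement (px) from the initial center.
#' @return list with `center`, `value` (objective at the optimum), `lambda`,
#'   and `converged`.
#' @export
optimize_center <- function(tile, initial_center = NULL, opt_radius = 14,
                            dk = 1, bounds = 8, lambda = NULL) {
  px <- tile_pixels(tile)
  if (is.null(initial_center)) {
    initial_center <- if (inherits(tile, "bead_tile")) tile$nominal_center
    else c(ncol(px), nrow(px)) / 2
  }
  init <- as.numeric(initial_center)
  if (is.null(lambda)) {
    sc <- radial_scatter(px, init, opt_radius)
    gf <- .pspline_fit_cpp(sc$r, sc$intensity, max(sc$r), dk, -1)
    lambda <- gf$lambda
  }
  lim <- c(ncol(px) - 1, nrow(px) - 1)
  fn <- function(p) {
    if (any(abs(p - init) > bounds) || any(p < 0) || any(p > lim))
      return(1e12 * (1 + sum(pmax(abs(p - init) - bounds, 0))))
    .profile_mse_cpp(px, p[1], p[2], opt_radius, dk, lambda)
  }
  # coarse grid pre-search: the objective has a spurious mirror-side local
  # minimum when the bead sits several pixels from the initial center
  gs <- seq(-0.75 * bounds, 0.75 * bounds, length.out = 5)
  start <- init
  sv <- fn(init)
  for (gx in gs) for (gy in gs) {
    v <- fn(init + c(gx, gy))
    if (v < sv) { sv <- v; start <- init + c(gx, gy) }
  }
  o1 <- optim(start, fn, method = "Nelder-Mead",
              control = list(maxit = 200, reltol = 1e-8))
  # restart with a small simplex for sub-pixel refinement
  o2 <- optim(o1$par, fn, method = "Nelder-Mead",
              control = list(maxit = 120, reltol = 1e-9,
                             parscale = c(0.15, 0.15)))
  best <- if (o2$value <= o1$value) o2 else o1
  list(center = as.numeric(best$par), value = best$value, lambda = lambda,
       converged = best$convergence == 0)
}

#' Extract SS and CI features from a fitted radial profile
#'
#' The background level is the mean of the fitted spline over distances
#' `bg_range` (20-40 px) from the center; if the scatter does not reach
#' 40 px the window shrinks to `[20, max distance]` and the result is
#' flagged. The steepest slope SS is the signed spline derivative farthest
#' from zero over `slope_range` (the bead rim region), divided by the
#' background; the center intensity CI is the spline value at 1 px from the
#' center divided by the background. Both are therefore invariant to
#' multiplicative exposure changes (absent saturation).
#'
#' @param fit a `profile_fit` from [profile_sse()].
#' @param slope_range distances (px) searched for the steepest slope.
#' @param bg_range distances (px) averaged for the background level.
#' @return list with `ss`, `ci`, `background`, `saturated_count`,
#'   `bg_window_shrunk`.
#' @export
extract_features <- function(fit, slope_range = c(3, 15),
                             bg_range = c(20, 40)) {
  stopifnot(inherits(fit, "profile_fit"))
  dmax <- fit$xmax
  hi <- min(bg_range[2], dmax)
  shrunk <- hi < bg_range[2]
  if (hi <= bg_range[1])
    refp_stop("feature_failure",
              "scatter too short for background window (max distance %.1f px)",
              dmax)
  bgrid <- seq(bg_range[1], hi, by = 0.1)
  background <- mean(predict(fit, bgrid))
  if (!is.finite(background) || background <= 0)
    refp_stop("feature_failure", "non-positive background level")
  sgrid <- seq(slope_range[1], min(slope_range[2], dmax), by = 0.05)
  dvals <- predict(fit, sgrid, deriv = 1)
  ss <- dvals[which.max(abs(dvals))] / background
  ci <- predict(fit, 1) / background
  list(ss = ss, ci = ci, background = background,
       saturated_count = fit$saturated_count, bg_window_shrunk = shrunk)
}

#' Detect beads in an image and compute per-bead features
#'
#' Full per-image feature pipeline: detection, tile cropping, continuous
#' center optimization, radial spline fit and SS/CI feature extraction.
#'
#' @param image field-of-view image matrix.
#' @param key list identifying the acquisition: `experiment`, `exposure_ms`,
#'   `fov`, `z_um`.
#' @param tile_size tile side in px.
#' @param pct detection threshold percentile.
#' @param keep_tiles return the cropped tiles alongside the feature table.
#' @param ... further arguments to [filter_clusters()].
#' @return data.frame with one row per accepted bead (experiment,
#'   exposure_ms, fov, z_um, bead_id, x, y, ss, ci, background,
#'   saturated_count). With `keep_tiles = TRUE`, a list
#'   `(features, tiles)`.
#' @export
bead_features <- function(image, key = list(experiment = "exp",
                                            exposure_ms = NA_real_,
                                            fov = 1, z_um = NA_real_),
                          tile_size = 64, pct = 1, keep_tiles = FALSE, ...) {
  det <- detect_beads(image, pct, ...)
  acc <- det[det$accepted, , drop = FALSE]
  rows <- list(); tiles <- list()
  if (nrow(acc) > 0) {
    for (b in seq_len(nrow(acc))) {
      tl <- crop_tile(image, c(acc$x[b], acc$y[b]), tile_size, key = key,
                      bead_id = b)
      ctr <- optimize_center(tl)
      ft <- profile_sse(tl, ctr$center)
      fe <- extract_features(ft)
      rows[[b]] <- data.frame(
        experiment = key$experiment, exposure_ms = key$exposure_ms,
        fov = key$fov, z_um = key$z_um, bead_id = b,
        x = ctr$center[1] + tl$offset[["x"]],
        y = ctr$center[2] + tl$offset[["y"]],
        ss = fe$ss, ci = fe$ci, background = fe$background,
        saturated_count = fe$saturated_count)
      if (keep_tiles) tiles[[b]] <- tl
    }
  }
  features <- if (length(rows)) do.call(rbind, rows) else
    data.frame(experiment = character(0), exposure_ms = numeric(0),
               fov = integer(0), z_um = numeric(0), bead_id = integer(0),
               x = numeric(0), y = numeric(0), ss = numeric(0),
               ci = numeric(0), background = numeric(0),
               saturated_count = integer(0))
  if (keep_tiles) list(features = features, tiles = tiles) else features
}

#' Run the feature pipeline over a dataset manifest
#'
#' @param manifest a manifest data.frame from [load_manifest()] or
#'   [generate_sweep()].
#' @param image_dir directory the manifest paths are relative to.
#' @param ... passed to [bead_features()].
#' @param keep_tiles also return all cropped tiles.
#' @return features data.frame over all manifest rows (and `tiles` when
#'   requested).
#' @export
features_for_manifest <- function(manifest, image_dir = ".",
                                  keep_tiles = FALSE, ...) {
  out <- list(); tiles <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    img <- read_image(file.path(image_dir, row$path))
    key <- list(experiment = row$experiment, exposure_ms = row$exposure_ms,
                fov = row$fov, z_um = row$z_um)
    fe <- bead_features(img, key, keep_tiles = keep_tiles, ...)
    if (keep_tiles) {
      out[[i]] <- fe$features
      tiles <- c(tiles, fe$tiles)
    } else out[[i]] <- fe
  }
  features <- do.call(rbind, out)
  if (keep_tiles) list(features = features, tiles = tiles) else features
}
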