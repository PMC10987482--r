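#' Interquartile-range outlier filter
#'
#' Keeps values inside `[Q1 - k*IQR, Q3 + k*IQR]`, with quartiles computed
#' by linear interpolation between order statistics (type 7). With fewer
#' than four values everything is kept.
#'
#' @param values numeric vector.
#' @param k fence multiplier (default 1.5).
#' @return logical mask of kept values.
#' @export
iqr_filter <- function(values, k = 1.5) {
  if (length(values) == 0) refp_stop("invalid_argument", "no values")
  if (length(values) < 4) return(rep(TRUE, length(values)))
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values >= q[1] - k * iqr & values <= q[2] + k * iqr
}

#' Median bead saturation flag: saturation of the middle bead image(s) when
#' kept beads are sorted by feature value (OR of the two middle ones for an
#' even count).
#' @noRd
median_saturated <- function(values, saturated) {
  n <- length(values)
  if (n == 0) return(NA)
  ord <- order(values)
  mid <- if (n %% 2 == 1) ord[(n + 1) / 2] else ord[c(n / 2, n / 2 + 1)]
  any(saturated[mid] > 0)
}

#' Build per-sweep median feature curves
#'
#' For each (experiment, exposure, fov) combination and each acquired Z,
#' applies the IQR outlier filter to the per-bead SS and CI values, records
#' the median of the kept beads, and flags the point as saturated when the
#' median bead image (sorted by that feature; both middle ones for an even
#' count) contains at least one saturated pixel.
#'
#' @param features features table from [bead_features()].
#' @param k IQR multiplier for the per-Z outlier filter.
#' @param min_z_levels minimum usable Z levels per curve.
#' @return list of `sweep_curve` objects, each with `key` and a `points`
#'   data.frame (z_um, median_ss, median_ci, sat_ss, sat_ci, n_beads,
#'   n_kept_ss, n_kept_ci).
#' @export
build_sweep_curve <- function(features, k = 1.5, min_z_levels = 3) {
  ks <- key_string(features$experiment, features$exposure_ms, features$fov)
  out <- list()
  for (kk in unique(ks)) {
    sub <- features[ks == kk, , drop = FALSE]
    zs <- sort(unique(sub$z_um))
    if (length(zs) < min_z_levels)
      refp_stop("curve_failure",
                "only %d usable Z levels for %s (need >= %d)",
                length(zs), kk, min_z_levels)
    pts <- lapply(zs, function(z) {
      g <- sub[sub$z_um == z, , drop = FALSE]
      kss <- iqr_filter(g$ss, k)
      kci <- iqr_filter(g$ci, k)
      data.frame(
        z_um = z,
        median_ss = median(g$ss[kss]),
        median_ci = median(g$ci[kci]),
        sat_ss = median_saturated(g$ss[kss], g$saturated_count[kss]),
        sat_ci = median_saturated(g$ci[kci], g$saturated_count[kci]),
        n_beads = nrow(g), n_kept_ss = sum(kss), n_kept_ci = sum(kci))
    })
    first <- features[ks == kk, ][1, ]
    out[[kk]] <- structure(list(
      key = list(experiment = first$experiment,
                 exposure_ms = first$exposure_ms, fov = first$fov),
      points = do.call(rbind, pts)), class = "sweep_curve")
  }
  out
}

#' @export
print.sweep_curve <- function(x, ...) {
  cat(sprintf("<sweep_curve> %s exposure %g ms fov %s: %d Z levels\n",
              x$key$experiment, x$key$exposure_ms, x$key$fov,
              nrow(x$points)))
  invisible(x)
}

#' Unsaturated (z, value) points of one feature of a curve
#' @noRd
curve_points <- function(curve, feature = c("ss", "ci"),
                         drop_saturated = TRUE) {
  feature <- match.arg(feature)
  p <- curve$points
  y <- if (feature == "ss") p$median_ss else p$median_ci
  sat <- if (feature == "ss") p$sat_ss else p$sat_ci
  keep <- if (drop_saturated) !sat else rep(TRUE, nrow(p))
  data.frame(z = p$z_um[keep], y = y[keep])
}

#' Smoothing-spline function through a curve's unsaturated points
#' @noRd
curve_fn <- function(obj, feature) {
  if (inherits(obj, "pooled_profile")) {
    fit <- obj$fit
    rng <- obj$range
  } else {
    pts <- curve_points(obj, feature)
    if (nrow(pts) < 4)
      refp_stop("alignment_failure",
                "fewer than 4 unsaturated points in curve")
    fit <- smooth.spline(pts$z, pts$y)
    rng <- range(pts$z)
  }
  list(fn = function(z) predict(fit, z)$y, range = rng)
}

#' Align one feature curve to another by shift and scale
#'
#' Least-squares fit of `scale * moving(z - shift)` to the fixed curve's
#' unsaturated median feature values: a grid search over the shift (closed
#' form optimal scale at each shift) followed by local refinement. Saturated
#' points never participate.
#'
#' @param moving a `sweep_curve` or `pooled_profile` supplying the template
#'   function.
#' @param fixed a `sweep_curve` whose points are fitted.
#' @param feature "ss" or "ci".
#' @param shift_grid_step grid resolution (um); default is a quarter of the
#'   fixed curve's Z increment.
#' @param min_overlap minimum number of fixed points that must fall inside
#'   the moving template's support for a shift to be admissible.
#' @param min_overlap_frac minimum fraction of the fixed curve's
#'   unsaturated points that a candidate shift must cover. Without this
#'   floor, a large shift that overlaps only the flat tails of two peaked
#'   curves can match them with a near-zero residual.
#' @return list with `shift_um`, `scale`, `residual` (mean squared), and
#'   `n_points`.
#' @export
align_curves <- function(moving, fixed, feature = c("ss", "ci"),
                         shift_grid_step = NULL, min_overlap = 4,
                         min_overlap_frac = 0.7) {
  feature <- match.arg(feature)
  mv <- curve_fn(moving, feature)
  fp <- curve_points(fixed, feature)
  if (nrow(fp) < min_overlap)
    refp_stop("alignment_failure",
              "fixed curve has only %d unsaturated points", nrow(fp))
  min_overlap <- max(min_overlap, ceiling(min_overlap_frac * nrow(fp)))
  zinc <- median(diff(sort(unique(fixed$points$z_um))))
  step <- shift_grid_step %||% (zinc / 4)
  span <- (max(fp$z) - min(fp$z)) / 2 +
    (mv$range[2] - mv$range[1]) / 2
  shifts <- seq(-span, span, by = step)
  eval_shift <- function(s) {
    zq <- fp$z - s
    ok <- zq >= mv$range[1] & zq <= mv$range[2]
    if (sum(ok) < min_overlap) return(NULL)
    m <- mv$fn(zq[ok]); y <- fp$y[ok]
    den <- sum(m * m)
    if (den < 1e-12) return(NULL)
    a <- sum(y * m) / den
    list(resid = mean((y - a * m)^2), scale = a, n = sum(ok))
  }
  best <- NULL; best_s <- NA_real_
  for (s in shifts) {
    r <- eval_shift(s)
    if (!is.null(r) && (is.null(best) || r$resid < best$resid)) {
      best <- r; best_s <- s
    }
  }
  if (is.null(best))
    refp_stop("alignment_failure", "no admissible shift found")
  refine <- optimize(function(s) {
    r <- eval_shift(s)
    if (is.null(r)) Inf else r$resid
  }, interval = c(best_s - step, best_s + step))
  if (is.finite(refine$objective) && refine$objective < best$resid) {
    best_s <- refine$minimum
    best <- eval_shift(best_s)
  }
  list(shift_um = best_s, scale = best$scale, residual = best$resid,
       n_points = best$n)
}

#' Pool aligned feature curves into a template profile
#'
#' Chooses a reference combination (the curve with the most unsaturated
#' points; ties broken by lowest exposure), aligns every other curve to it
#' (shift in Z, scale in feature value), and fits one cubic smoothing
#' spline to the union of aligned unsaturated points. The pooled profile is
#' the template used to locate feature extrema for every individual curve.
#'
#' @param curves list of `sweep_curve` objects (from [build_sweep_curve()]).
#' @param feature "ss" or "ci".
#' @param reference_key optional name (as in `names(curves)`) of the curve
#'   to use as reference.
#' @return an object of class `pooled_profile`.
#' @export
build_pooled_profile <- function(curves, feature = c("ss", "ci"),
                                 reference_key = NULL) {
  feature <- match.arg(feature)
  if (length(curves) == 0) refp_stop("invalid_argument", "no curves")
  if (is.null(names(curves)) || any(!nzchar(names(curves))))
    names(curves) <- vapply(curves, function(cv)
      key_string(cv$key$experiment, cv$key$exposure_ms, cv$key$fov), "")
  if (is.null(reference_key)) {
    n_unsat <- vapply(curves, function(cv) nrow(curve_points(cv, feature)),
                      0L)
    expo <- vapply(curves, function(cv) cv$key$exposure_ms, 0)
    reference_key <- names(curves)[order(-n_unsat, expo)][1]
  }
  if (!reference_key %in% names(curves))
    refp_stop("invalid_argument", "reference_key not among curves")
  ref <- curves[[reference_key]]
  pooled <- list(); aligns <- list()
  for (nm in names(curves)) {
    cv <- curves[[nm]]
    pts <- curve_points(cv, feature)
    if (nm == reference_key) {
      al <- list(shift_um = 0, scale = 1, residual = 0,
                 n_points = nrow(pts))
    } else {
      al <- tryCatch(align_curves(cv, ref, feature),
                     error = function(e) {
                       warning("dropping curve ", nm, " from pooled profile: ",
                               conditionMessage(e))
                       NULL
                     })
      if (is.null(al)) next
    }
    pooled[[nm]] <- data.frame(z = pts$z + al$shift_um,
                               y = al$scale * pts$y)
    aligns[[nm]] <- data.frame(key = nm, shift_um = al$shift_um,
                               scale = al$scale, residual = al$residual)
  }
  if (length(pooled) == 0)
    refp_stop("alignment_failure", "all curves failed alignment")
  dat <- do.call(rbind, pooled)
  # aligned curves cluster their z values within a fraction of the sweep
  # increment; cap the knots at the sweep resolution so the spline cannot
  # oscillate between near-duplicate abscissae
  nk <- max(5L, length(unique(ref$points$z_um)))
  nk <- min(nk, length(unique(dat$z)))
  fit <- smooth.spline(dat$z, dat$y, nknots = nk)
  structure(list(feature = feature, reference_key = reference_key,
                 fit = fit, range = range(dat$z),
                 alignments = do.call(rbind, aligns),
                 n_curves = length(pooled)),
            class = "pooled_profile")
}

#' @export
print.pooled_profile <- function(x, ...) {
  cat(sprintf(
    "<pooled_profile> %s: %d curves pooled, reference %s, z range [%g, %g]\n",
    toupper(x$feature), x$n_curves, x$reference_key, x$range[1], x$range[2]))
  invisible(x)
}

#' Evaluate a pooled profile
#' @param object a `pooled_profile`.
#' @param z focal plane values (um).
#' @param ... unused.
#' @export
predict.pooled_profile <- function(object, z, ...) {
  predict(object$fit, z)$y
}

#' Feature-specific REFP of one sweep curve
#'
#' Fits the pooled profile to the curve (shift in Z, scale in feature,
#' saturated points excluded) and returns the Z at which the fitted profile
#' is minimized (SS) or maximized (CI), located on a fine grid across the
#' curve's Z range.
#'
#' @param pooled a `pooled_profile`.
#' @param curve a `sweep_curve`.
#' @param grid_step extremum search resolution (um); default
#'   z_increment / 100.
#' @return list with `refp_um`, `boundary_warning`, `shift_um`, `scale`.
#' @export
feature_refp <- function(pooled, curve, grid_step = NULL) {
  stopifnot(inherits(pooled, "pooled_profile"), inherits(curve, "sweep_curve"))
  feature <- pooled$feature
  al <- align_curves(pooled, curve, feature)
  zr <- range(curve$points$z_um)
  zinc <- median(diff(sort(unique(curve$points$z_um))))
  step <- grid_step %||% (zinc / 100)
  zg <- seq(zr[1], zr[2], by = step)
  ok <- zg - al$shift_um >= pooled$range[1] &
    zg - al$shift_um <= pooled$range[2]
  if (!any(ok))
    refp_stop("alignment_failure", "aligned profile does not cover the sweep")
  zg <- zg[ok]
  g <- al$scale * predict(pooled, zg - al$shift_um)
  i <- if (feature == "ss") which.min(g) else which.max(g)
  list(refp_um = zg[i],
       boundary_warning = i == 1L || i == length(zg),
       shift_um = al$shift_um, scale = al$scale)
}

#' Final REFP from the two feature-specific estimates
#'
#' @param refp_ss,refp_ci feature-specific REFP values (um).
#' @return their arithmetic mean.
#' @export
compute_refp <- function(refp_ss, refp_ci) {
  if (!is.finite(refp_ss) || !is.finite(refp_ci))
    refp_stop("invalid_argument", "non-finite feature REFP")
  (refp_ss + refp_ci) / 2
}

#' Estimate the REFP for every sweep combination in a features table
#'
#' Runs the full REFP pipeline: per-combination median curves with IQR
#' outlier removal, per-feature pooled profiles, feature-specific REFPs and
#' the final REFP `(REFP_SS + REFP_CI) / 2` per (experiment, exposure, fov).
#'
#' @param features features table from [bead_features()] /
#'   [features_for_manifest()].
#' @param k IQR multiplier.
#' @return data.frame (experiment, exposure_ms, fov, refp_ss, refp_ci,
#'   refp_final, boundary_warning) with the pooled profiles attached as
#'   attribute `"pooled"`.
#' @export
estimate_refp <- function(features, k = 1.5) {
  curves <- build_sweep_curve(features, k = k)
  pooled <- list(ss = build_pooled_profile(curves, "ss"),
                 ci = build_pooled_profile(curves, "ci"))
  rows <- lapply(curves, function(cv) {
    tryCatch({
      fss <- feature_refp(pooled$ss, cv)
      fci <- feature_refp(pooled$ci, cv)
      data.frame(experiment = cv$key$experiment,
                 exposure_ms = cv$key$exposure_ms, fov = cv$key$fov,
                 refp_ss = fss$refp_um, refp_ci = fci$refp_um,
                 refp_final = compute_refp(fss$refp_um, fci$refp_um),
                 boundary_warning = fss$boundary_warning ||
                   fci$boundary_warning)
    }, error = function(e) {
      warning("no REFP for combination ",
              key_string(cv$key$experiment, cv$key$exposure_ms, cv$key$fov),
              ": ", conditionMessage(e))
      NULL
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pooled") <- pooled
  out
}
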