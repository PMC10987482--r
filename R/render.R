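sigmoid <- function(x) 1 / (1 + exp(-x))

#' Normalized (background = 1) sharp scene before defocus blur.
#' beads: data.frame(x, y); distractors: data.frame(x, y, a, b, theta).
#' Coordinates 0-based, x = column, y = row.
#' @noRd
render_base <- function(width, height, beads, distractors, dz, model) {
  img <- matrix(1, nrow = height, ncol = width)
  w <- model$edge_width_px
  halo_amp <- model$halo_gain * sigmoid(dz / model$focus_sharpness_scale)
  r_ext <- ceiling(model$halo_radius_px + 4 * model$halo_sigma_px)
  if (nrow(beads) > 0) {
    for (b in seq_len(nrow(beads))) {
      cx <- beads$x[b]; cy <- beads$y[b]
      j0 <- max(0, floor(cx - r_ext)); j1 <- min(width - 1, ceiling(cx + r_ext))
      i0 <- max(0, floor(cy - r_ext)); i1 <- min(height - 1, ceiling(cy + r_ext))
      if (j1 < j0 || i1 < i0) next
      jj <- j0:j1; ii <- i0:i1
      r <- sqrt(outer((ii - cy)^2, (jj - cx)^2, `+`))
      body <- sigmoid((r - model$rim_inner_px) / w) *
        sigmoid((model$bead_radius_px - r) / w)
      halo <- exp(-(r - model$halo_radius_px)^2 / (2 * model$halo_sigma_px^2))
      img[ii + 1, jj + 1] <- img[ii + 1, jj + 1] -
        model$rim_depth * body + halo_amp * halo
    }
  }
  if (!is.null(distractors) && nrow(distractors) > 0) {
    for (d in seq_len(nrow(distractors))) {
      cx <- distractors$x[d]; cy <- distractors$y[d]
      a <- distractors$a[d]; bb <- distractors$b[d]; th <- distractors$theta[d]
      ext <- ceiling(a + 3)
      j0 <- max(0, floor(cx - ext)); j1 <- min(width - 1, ceiling(cx + ext))
      i0 <- max(0, floor(cy - ext)); i1 <- min(height - 1, ceiling(cy + ext))
      if (j1 < j0 || i1 < i0) next
      jj <- j0:j1; ii <- i0:i1
      dx <- outer(rep(1, length(ii)), jj - cx)
      dy <- outer(ii - cy, rep(1, length(jj)))
      xr <- cos(th) * dx + sin(th) * dy
      yr <- -sin(th) * dx + cos(th) * dy
      re <- sqrt((xr / a)^2 + (yr / bb)^2)
      # smooth elongated dark blob
      img[ii + 1, jj + 1] <- img[ii + 1, jj + 1] -
        0.65 * sigmoid((1 - re) * a / w)
    }
  }
  img
}

#' Signed-dz disk blur radius in px
#' @noRd
blur_radius <- function(dz, model) {
  model$defocus_blur_rate * abs(dz) * (1 + model$blur_asym * sign(dz))
}

#' Render the full scene at a given dz and exposure; returns an integer
#' matrix in [0, bit_depth_max].
#' @noRd
render_scene <- function(width, height, beads, distractors, dz, exposure,
                         model, seed = NULL) {
  if (width <= 0 || height <= 0)
    refp_stop("invalid_argument", "non-positive image size")
  if (exposure <= 0)
    refp_stop("invalid_argument", "exposure must be positive")
  gain <- model$background_level * exposure / model$exposure_ref_ms
  img <- render_base(width, height, beads, distractors, dz, model) * gain
  rb <- blur_radius(dz, model)
  if (rb > 0) {
    # the pre-noise background is flat and blur-invariant, so only object
    # neighbourhoods need the disk convolution
    R <- ceiling(rb + 1)
    r_bead <- ceiling(model$halo_radius_px + 4 * model$halo_sigma_px) + R + 1
    rects <- list()
    if (nrow(beads) > 0)
      rects <- c(rects, lapply(seq_len(nrow(beads)), function(b)
        c(beads$x[b], beads$y[b], r_bead)))
    if (!is.null(distractors) && nrow(distractors) > 0)
      rects <- c(rects, lapply(seq_len(nrow(distractors)), function(d)
        c(distractors$x[d], distractors$y[d],
          ceiling(distractors$a[d] + 3) + R + 1)))
    if (length(rects) == 0) {
      img <- .disk_blur_cpp(img, rb)
    } else {
      # compute every blurred core from the unmodified image, then paste
      cores <- lapply(rects, function(rc) {
        j0 <- max(0, floor(rc[1] - rc[3])); j1 <- min(width - 1, ceiling(rc[1] + rc[3]))
        i0 <- max(0, floor(rc[2] - rc[3])); i1 <- min(height - 1, ceiling(rc[2] + rc[3]))
        # extend by the kernel radius so the core matches a full-image blur
        je0 <- max(0, j0 - R); je1 <- min(width - 1, j1 + R)
        ie0 <- max(0, i0 - R); ie1 <- min(height - 1, i1 + R)
        sub <- .disk_blur_cpp(img[(ie0:ie1) + 1, (je0:je1) + 1, drop = FALSE],
                              rb)
        list(i = (i0:i1) + 1, j = (j0:j1) + 1,
             core = sub[(i0 - ie0) + seq_len(i1 - i0 + 1),
                        (j0 - je0) + seq_len(j1 - j0 + 1), drop = FALSE])
      })
      for (co in cores) img[co$i, co$j] <- co$core
    }
  }
  # bright bead centers: added after the disk blur with an analytically
  # equivalent Gaussian defocus, so center intensity varies smoothly in dz
  if (nrow(beads) > 0) {
    s2 <- model$center_sigma_px^2
    sd2 <- rb^2 / 2
    amp <- gain * model$center_peak_gain * s2 / (s2 + sd2)
    se2 <- s2 + sd2
    r_ext <- ceiling(4 * sqrt(se2))
    for (b in seq_len(nrow(beads))) {
      cx <- beads$x[b]; cy <- beads$y[b]
      j0 <- max(0, floor(cx - r_ext)); j1 <- min(width - 1, ceiling(cx + r_ext))
      i0 <- max(0, floor(cy - r_ext)); i1 <- min(height - 1, ceiling(cy + r_ext))
      if (j1 < j0 || i1 < i0) next
      jj <- j0:j1; ii <- i0:i1
      r2 <- outer((ii - cy)^2, (jj - cx)^2, `+`)
      img[ii + 1, jj + 1] <- img[ii + 1, jj + 1] + amp * exp(-r2 / (2 * se2))
    }
  }
  with_seed(seed, {
    if (model$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), sd = model$noise_sd),
                          nrow = height)
    matrix(as.integer(clamp(round(img), 0, model$bit_depth_max)),
           nrow = height)
  })
}

#' Render a single bead tile
#'
#' Renders one bead at signed defocus `dz` on a square tile. Mainly used for
#' testing and for inspecting the optical model; full fields of view are
#' produced by [render_field()].
#'
#' @param dz signed distance (um) from the focal plane; negative is below.
#' @param exposure exposure time (ms).
#' @param model an [optical_model()].
#' @param tile_size tile side in px (at least 4x the bead radius).
#' @param center continuous bead center `c(x, y)`, 0-based; defaults to the
#'   tile midpoint.
#' @param seed optional seed for the noise draw.
#' @return integer matrix `tile_size x tile_size` with values in
#'   `[0, bit_depth_max]`.
#' @export
render_bead <- function(dz, exposure, model = optical_model(),
                        tile_size = 64, center = NULL, seed = NULL) {
  if (tile_size <= 0 || exposure <= 0)
    refp_stop("invalid_argument",
              "tile_size and exposure must be positive")
  if (tile_size < 4 * model$bead_radius_px)
    refp_stop("invalid_argument", "tile_size < 4 * bead_radius_px")
  if (is.null(center)) center <- c(tile_size / 2, tile_size / 2)
  beads <- data.frame(x = center[1], y = center[2])
  render_scene(tile_size, tile_size, beads, NULL, dz, exposure, model, seed)
}

#' Place beads and distractors without overlap by rejection sampling
#' @noRd
place_objects <- function(width, height, n_beads, n_distractors, model,
                          seed = NULL, margin = NULL, min_sep = NULL,
                          max_tries = 4000) {
  margin <- margin %||% ceiling(model$halo_radius_px +
                                  4 * model$halo_sigma_px + 12)
  min_sep <- min_sep %||% (2 * model$halo_radius_px + 10)
  with_seed(seed, {
    pts <- matrix(numeric(0), ncol = 2)
    n_total <- n_beads + n_distractors
    tries <- 0
    while (nrow(pts) < n_total) {
      if (tries > max_tries)
        refp_stop("placement_failure",
                  "could not place %d objects in a %dx%d field",
                  n_total, width, height)
      tries <- tries + 1
      p <- c(runif(1, margin, width - 1 - margin),
             runif(1, margin, height - 1 - margin))
      if (nrow(pts) == 0 ||
          all(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= min_sep))
        pts <- rbind(pts, p)
    }
    beads <- data.frame(x = numeric(0), y = numeric(0))
    if (n_beads > 0)
      beads <- data.frame(x = pts[seq_len(n_beads), 1],
                          y = pts[seq_len(n_beads), 2])
    distractors <- NULL
    if (n_distractors > 0) {
      idx <- n_beads + seq_len(n_distractors)
      distractors <- data.frame(
        x = pts[idx, 1], y = pts[idx, 2],
        a = runif(n_distractors, 12, 16),
        b = runif(n_distractors, 3.5, 5),
        theta = runif(n_distractors, 0, pi))
    }
    list(beads = beads, distractors = distractors)
  })
}

#' Render a field of view with known ground truth
#'
#' Places `n_beads` beads (continuous sub-pixel centers, no overlaps) plus
#' optional elongated dark distractors, and renders the field at the given
#' defocus and exposure.
#'
#' @inheritParams render_bead
#' @param n_beads number of beads.
#' @param n_distractors number of elongated debris objects (these fail the
#'   circularity filter by construction).
#' @param width,height image size in px.
#' @param seed seed controlling both placement and noise. Alternatively pass
#'   `placement` (result of a previous call) to keep positions fixed while
#'   re-rendering at other `dz`/`exposure` values.
#' @param placement optional list with `beads` and `distractors` data frames.
#' @param noise_seed optional separate seed for the noise draw.
#' @return a list with `image` (integer matrix) and `truth` (data.frame of
#'   bead centers: bead_id, x, y) plus the `placement` used.
#' @export
render_field <- function(dz, exposure, model = optical_model(),
                         n_beads = 8, n_distractors = 0,
                         width = 768, height = 640, seed = NULL,
                         placement = NULL, noise_seed = NULL) {
  if (is.null(placement))
    placement <- place_objects(width, height, n_beads, n_distractors, model,
                               seed = seed)
  ns <- noise_seed %||% (if (is.null(seed)) NULL else mix_seed(seed, 7919))
  img <- render_scene(width, height, placement$beads, placement$distractors,
                      dz, exposure, model, seed = ns)
  truth <- cbind(data.frame(bead_id = seq_len(nrow(placement$beads))),
                 placement$beads)
  list(image = img, truth = truth, placement = placement)
}

#' Generate a synthetic Z sweep on disk
#'
#' Writes one image per (Z, exposure, FOV) combination plus a manifest CSV
#' with columns experiment, exposure_ms, fov, z_um, path and true_dz_um
#' (`z - true_refp`; negative below the REFP). Bead placement is drawn once
#' per field of view and held fixed across the sweep.
#'
#' @param spec a [sweep_spec()].
#' @param model an [optical_model()].
#' @param out_dir output directory (created if needed).
#' @param format "tiff" or "png".
#' @return the manifest as a data.frame (invisibly written to
#'   `out_dir/manifest.csv`).
#' @export
generate_sweep <- function(spec, model = optical_model(),
                           out_dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  ext <- if (format == "tiff") "tif" else "png"
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    refp_stop("io_error", "cannot create output directory %s", out_dir)
  placements <- lapply(seq_len(spec$n_fov), function(f)
    place_objects(spec$image_width, spec$image_height, spec$beads_per_fov,
                  spec$distractor_count, model,
                  seed = mix_seed(spec$seed, f)))
  rows <- list()
  for (f in seq_len(spec$n_fov)) {
    for (e in spec$exposures) {
      for (z in spec$z_levels) {
        dz <- z - spec$true_refp
        fr <- render_field(dz, e, model,
                           width = spec$image_width,
                           height = spec$image_height,
                           placement = placements[[f]],
                           noise_seed = mix_seed(spec$seed, f, e * 1000, z * 10))
        fn <- sprintf("%s_e%03d_f%02d_z%09.1f.%s", spec$experiment, e, f, z,
                      ext)
        write_image(fr$image, file.path(out_dir, fn))
        rows[[length(rows) + 1]] <- data.frame(
          experiment = spec$experiment, exposure_ms = e, fov = f, z_um = z,
          path = fn, true_dz_um = dz)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
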