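# Shared fixtures: all synthetic inputs are generated in code at test time.

default_model <- function(...) optical_model(...)

# render a features table for a compact in-memory Z sweep (no disk I/O)
sweep_features <- function(model = optical_model(), true_refp = 1507.5,
                           z_span = 45, z_increment = 7.5,
                           exposures = c(6, 12, 15), n_fov = 1,
                           beads_per_fov = 8, seed = 1,
                           width = 768, height = 640, keep_tiles = FALSE) {
  zs <- seq(true_refp - z_span, true_refp + z_span, by = z_increment)
  rows <- list()
  tiles <- list()
  for (f in seq_len(n_fov)) {
    pl <- refplane:::place_objects(width, height, beads_per_fov, 0, model,
                                   seed = refplane:::mix_seed(seed, f))
    for (e in exposures) {
      for (z in zs) {
        fr <- render_field(z - true_refp, e, model, width = width,
                           height = height, placement = pl,
                           noise_seed = refplane:::mix_seed(seed, f, e, z * 10))
        fe <- bead_features(fr$image,
                            list(experiment = paste0("sweep", seed),
                                 exposure_ms = e, fov = f, z_um = z),
                            keep_tiles = keep_tiles)
        if (keep_tiles) {
          rows[[length(rows) + 1]] <- fe$features
          tiles <- c(tiles, fe$tiles)
        } else {
          rows[[length(rows) + 1]] <- fe
        }
      }
    }
  }
  features <- do.call(rbind, rows)
  if (keep_tiles) list(features = features, tiles = tiles) else features
}

# analytic sweep_curve with a Gaussian CI peak / negative SS trough
analytic_curve <- function(zs, peak_z, experiment = "a", exposure_ms = 10,
                           fov = 1, scale = 1, noise_sd = 0, seed = NULL,
                           saturated = rep(FALSE, length(zs))) {
  ci <- scale * (1 + exp(-(zs - peak_z)^2 / (2 * 25^2)))
  ss <- -scale * (0.2 + 0.3 * exp(-(zs - peak_z)^2 / (2 * 25^2)))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    ci <- ci + rnorm(length(zs), sd = noise_sd)
    ss <- ss + rnorm(length(zs), sd = noise_sd)
  }
  structure(list(
    key = list(experiment = experiment, exposure_ms = exposure_ms, fov = fov),
    points = data.frame(z_um = zs, median_ss = ss, median_ci = ci,
                        sat_ss = saturated, sat_ci = saturated,
                        n_beads = 8, n_kept_ss = 8, n_kept_ci = 8)),
    class = "sweep_curve")
}

# draw a filled shape directly (dark on bright background) for closed-form
# detector geometry tests
shape_image <- function(width, height, fg = 40, bg = 200,
                        shape = c("disk", "square", "ellipse"),
                        cx, cy, r = 10, side = 20, a = 15, b = 4) {
  shape <- match.arg(shape)
  img <- matrix(bg, nrow = height, ncol = width)
  x <- rep(0:(width - 1), each = height)
  y <- rep(0:(height - 1), times = width)
  sel <- switch(shape,
                disk = (x - cx)^2 + (y - cy)^2 <= r^2,
                square = abs(x - cx) <= side / 2 & abs(y - cy) <= side / 2,
                ellipse = ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1)
  img[sel] <- fg
  img
}

# mock ensemble member with a fixed per-tile prediction vector
mock_model <- function(values, label_range = NULL) {
  structure(list(values = values, label_range = label_range),
            class = "mock_dz_model")
}

predict.mock_dz_model <- function(object, tiles, ...) {
  n <- if (is.matrix(tiles)) nrow(tiles) else length(tiles)
  rep_len(object$values, n)
}
registerS3method("predict", "mock_dz_model", predict.mock_dz_model,
                 envir = environment())

# placeholder tile list for mock predictions
dummy_tiles <- function(n) replicate(n, matrix(0, 64, 64), simplify = FALSE)

# independent two-level aggregation oracle (no IQR removal kept separate)
two_level_mean <- function(pred_matrix, k = 1.5) {
  per_model <- apply(pred_matrix, 2, function(p) {
    if (length(p) >= 4) {
      q <- quantile(p, c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      p <- p[p >= q[1] - k * iqr & p <= q[2] + k * iqr]
    }
    mean(p)
  })
  mean(per_model)
}
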