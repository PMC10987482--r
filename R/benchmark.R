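#' Render a Z sweep in memory and compute its per-bead feature table
#'
#' Convenience driver used by the synthetic validation studies: renders one
#' sweep (bead placement fixed per field of view), runs detection, center
#' optimization and feature extraction on every image, and returns the
#' features table (and tiles on request) without touching disk.
#'
#' @param model an [optical_model()].
#' @param experiment experiment identifier.
#' @param true_refp ground-truth focal plane (um).
#' @param z_span sweep half-range (um); levels are
#'   `true_refp +/- k * z_increment` up to the span.
#' @param z_increment sweep step (um).
#' @param exposures exposures (ms).
#' @param n_fov fields of view.
#' @param beads_per_fov beads per field.
#' @param seed base seed.
#' @param keep_tiles also return cropped tiles.
#' @param width,height field size (px).
#' @return features data.frame, or `list(features, tiles)`.
#' @export
render_sweep_features <- function(model = optical_model(),
                                  experiment = "sweep",
                                  true_refp = 1507.5, z_span = 45,
                                  z_increment = 7.5,
                                  exposures = c(6, 12, 15), n_fov = 2,
                                  beads_per_fov = 8, seed = 1,
                                  keep_tiles = FALSE,
                                  width = 768, height = 640) {
  n_side <- floor(z_span / z_increment)
  zs <- true_refp + z_increment * (-n_side:n_side)
  rows <- list(); tiles <- list()
  for (f in seq_len(n_fov)) {
    pl <- place_objects(width, height, beads_per_fov, 0, model,
                        seed = mix_seed(seed, f))
    for (e in exposures) {
      for (z in zs) {
        fr <- render_field(z - true_refp, e, model, width = width,
                           height = height, placement = pl,
                           noise_seed = mix_seed(seed, f, e * 100,
                                                 round(z * 10)))
        fe <- bead_features(fr$image,
                            list(experiment = experiment, exposure_ms = e,
                                 fov = f, z_um = z),
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

#' REFP recovery study on synthetic sweeps
#'
#' Generates `n_sweeps` independent synthetic Z sweeps with randomly drawn
#' true focal planes, runs the full feature and REFP pipeline on each, and
#' reports the signed REFP error per (sweep, exposure, fov) combination.
#'
#' @param n_sweeps number of independent sweeps.
#' @param seed base seed (drives placements, noise and the true REFPs).
#' @param model an [optical_model()]; set `noise_sd = 0` for the noise-free
#'   variant.
#' @param z_span,z_increment,exposures,n_fov,beads_per_fov sweep geometry.
#' @return data.frame with one row per (sweep, exposure, fov):
#'   `true_refp`, `refp_final`, `error_um`.
#' @export
benchmark_refp_recovery <- function(n_sweeps = 10, seed = 1,
                                    model = optical_model(),
                                    z_span = 37.5, z_increment = 7.5,
                                    exposures = c(6, 12, 15), n_fov = 2,
                                    beads_per_fov = 8) {
  out <- list()
  for (s in seq_len(n_sweeps)) {
    true_refp <- 1500 + with_seed(mix_seed(seed, s, 555),
                                  runif(1, -z_increment, z_increment))
    features <- render_sweep_features(
      model, experiment = sprintf("sweep%02d", s), true_refp = true_refp,
      z_span = z_span, z_increment = z_increment, exposures = exposures,
      n_fov = n_fov, beads_per_fov = beads_per_fov,
      seed = mix_seed(seed, s))
    refp <- estimate_refp(features)
    refp$true_refp <- true_refp
    refp$error_um <- refp$refp_final - true_refp
    out[[s]] <- refp
  }
  do.call(rbind, out)
}

#' Scaled-down single-image dZ prediction study
#'
#' End-to-end validation of the prediction pipeline at desk scale: trains a
#' reduced ensemble on one synthetic "instrument" (sweeps spanning
#' `+/- z_span_train` um, labels from the estimated REFP), then predicts dZ
#' for every acquisition of a held-out synthetic sweep (different true
#' focal plane, off-grid) using `beads_per_acquisition` beads with
#' SS-based outlier filtering and two-level (bead, model) averaging.
#'
#' Training uses the configured profile; by default every hyperparameter is
#' the package default except the initial learning rate (1e-3) and epoch
#' cap (60), the desk-scale compensation discussed in the methods vignette.
#'
#' @param seed base seed for all randomness.
#' @param n_models ensemble size.
#' @param model an [optical_model()].
#' @param config a [training_config()]; `NULL` for the desk-scale profile.
#' @param train_refp true focal plane of the training instrument (um).
#' @param test_refp_offset offset (um) of the held-out sweep's true focal
#'   plane; non-multiples of `z_increment` keep test dZ values off the
#'   training grid.
#' @param z_span_train,z_span_test sweep half-ranges (um); the test span
#'   stays inside the training dZ range.
#' @param z_increment sweep step (um).
#' @param exposures exposures (ms), shared by both sweeps.
#' @param n_fov_train,n_fov_test fields of view.
#' @param beads_per_fov beads rendered per field.
#' @param beads_per_acquisition beads used per prediction.
#' @return list with `predictions` (one row per test acquisition:
#'   true dZ, ensemble `dz_final`, single-model `dz_single`),
#'   `pct_within_7p5`, `pct_within_10`, `pct_within_10_single_worst`
#'   (worst exposure, single model), the trained `models`, and the
#'   training `refp` table.
#' @export
benchmark_dz_prediction <- function(seed = 1, n_models = 3,
                                    model = optical_model(),
                                    config = NULL,
                                    train_refp = 1507.5,
                                    test_refp_offset = 3.1,
                                    z_span_train = 60, z_span_test = 45,
                                    z_increment = 7.5,
                                    exposures = c(6, 12, 15),
                                    n_fov_train = 5, n_fov_test = 2,
                                    beads_per_fov = 8,
                                    beads_per_acquisition = 6) {
  config <- config %||% training_config(initial_learning_rate = 1e-3,
                                        max_epochs = 60,
                                        n_models = n_models,
                                        seed = mix_seed(seed, 77))
  config$n_models <- n_models
  # --- training instrument: sweeps, REFP, labeled tiles, ensemble ---
  tr <- render_sweep_features(model, experiment = "train",
                              true_refp = train_refp,
                              z_span = z_span_train,
                              z_increment = z_increment,
                              exposures = exposures, n_fov = n_fov_train,
                              beads_per_fov = beads_per_fov,
                              seed = mix_seed(seed, 1), keep_tiles = TRUE)
  refp <- estimate_refp(tr$features)
  dataset <- make_training_set(tr$tiles, refp, tr$features)
  models <- train_ensemble(dataset, config)

  # --- held-out sweep: per-acquisition six-bead predictions ---
  test_refp <- train_refp + test_refp_offset
  n_side <- floor(z_span_test / z_increment)
  zs <- test_refp + z_increment * (-n_side:n_side)
  rows <- list()
  for (f in seq_len(n_fov_test)) {
    pl <- place_objects(768, 640, beads_per_fov, 0, model,
                        seed = mix_seed(seed, 2, f))
    for (e in exposures) {
      for (z in zs) {
        fr <- render_field(z - test_refp, e, model, placement = pl,
                           noise_seed = mix_seed(seed, 2, f, e * 100,
                                                 round(z * 10)))
        fe <- bead_features(fr$image,
                            list(experiment = "test", exposure_ms = e,
                                 fov = f, z_um = z), keep_tiles = TRUE)
        keep <- iqr_filter(fe$features$ss)
        tl <- fe$tiles[keep]
        bgk <- fe$features$background[keep]
        nb <- min(beads_per_acquisition, length(tl))
        pr <- predict_dz(models, tl[seq_len(nb)],
                         background = bgk[seq_len(nb)])
        one <- pr$per_bead_per_model[, 1]
        single <- mean(one[iqr_filter(one)])
        rows[[length(rows) + 1]] <- data.frame(
          exposure_ms = e, fov = f, z_um = z,
          true_dz = z - test_refp, n_beads = nb,
          dz_final = pr$dz_final, dz_single = single)
      }
    }
  }
  pred <- do.call(rbind, rows)
  err <- abs(pred$dz_final - pred$true_dz)
  err1 <- abs(pred$dz_single - pred$true_dz)
  by_expo <- vapply(split(err1, pred$exposure_ms),
                    function(v) 100 * mean(v <= 10), 0)
  list(predictions = pred,
       pct_within_7p5 = 100 * mean(err < 7.5),
       pct_within_10 = 100 * mean(err <= 10),
       pct_within_10_single_worst = min(by_expo),
       pct_within_10_single_by_exposure = by_expo,
       models = models, refp = refp, dataset_size = nrow(dataset$x))
}
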