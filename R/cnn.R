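#' Training configuration for the dZ regression network
#'
#' Defaults are the selected values of the hyperparameter optimization:
#' initial learning rate 1e-4 dropped by a factor 0.9 every 15 epochs,
#' batch size 32 with an adaptive-moment (Adam) optimizer, a validation
#' test every 2000 steps on a 20% validation split with patience 10, and L2
#' weight decay 5e-4. No input normalization is the default
#' (`normalization_mode = "none"`), which gave the best accuracy among
#' none / z-score / zerocenter / average-background.
#'
#' `c1`, `c2` and `hidden` size the reduced-depth residual CNN backbone
#' (two residual blocks over 12 and 24 channels with a 48-unit head); the
#' backbone is deliberately small so that ensembles train on a single CPU.
#' `max_epochs` caps training in addition to early stopping.
#'
#' @param initial_learning_rate,lr_drop_period_epochs,lr_drop_factor learning
#'   rate schedule.
#' @param batch_size minibatch size.
#' @param validation_frequency_steps steps between validation evaluations.
#' @param validation_patience non-improving validations before stopping.
#' @param l2_weight_decay L2 regularization on weights.
#' @param validation_fraction fraction of tiles held out for validation.
#' @param n_models ensemble size.
#' @param normalization_mode one of "none", "zscore", "zerocenter",
#'   "avg_background".
#' @param network_input_px network input side (64); larger tiles are center
#'   cropped.
#' @param max_epochs epoch cap.
#' @param c1,c2,hidden backbone widths.
#' @param seed base seed; ensemble member m trains with `seed + m`.
#' @return a `training_config` list.
#' @export
training_config <- function(initial_learning_rate = 1e-4,
                            lr_drop_period_epochs = 15,
                            lr_drop_factor = 0.9,
                            batch_size = 32,
                            validation_frequency_steps = 2000,
                            validation_patience = 10,
                            l2_weight_decay = 5e-4,
                            validation_fraction = 0.2,
                            n_models = 10,
                            normalization_mode = c("none", "zscore",
                                                   "zerocenter",
                                                   "avg_background"),
                            network_input_px = 64,
                            max_epochs = 100,
                            c1 = 12, c2 = 24, hidden = 48,
                            seed = 1) {
  normalization_mode <- match.arg(normalization_mode)
  structure(as.list(environment()), class = "training_config")
}

#' Augmentation configuration
#'
#' Only sharpness-preserving augmentations are used: translation within
#' +/- 5 px, rotation within +/- 5 degrees, reflection, intensity jitter,
#' and scaling in `[0.95, 1.05]` (bilinear resampling, reflected borders).
#' No augmentation that changes image blurriness is available, since tile
#' blur is exactly the signal being regressed.
#'
#' @param translate_px maximum |translation| per axis (px).
#' @param rotate_deg maximum |rotation| (degrees).
#' @param reflection enable horizontal reflection.
#' @param jitter_amplitude relative intensity jitter amplitude.
#' @param scale scale range.
#' @param enabled master switch.
#' @return an `augmentation_config` list.
#' @export
augmentation_config <- function(translate_px = 5, rotate_deg = 5,
                                reflection = TRUE, jitter_amplitude = 0.05,
                                scale = c(0.95, 1.05), enabled = TRUE) {
  structure(as.list(environment()), class = "augmentation_config")
}

norm_mode_int <- function(mode) {
  match(mode, c("none", "zscore", "zerocenter", "avg_background")) - 1L
}

#' Normalize a tile for network input
#'
#' @param tile `bead_tile` or matrix of uint8 intensities.
#' @param mode "none" (identity), "zscore", "zerocenter" or
#'   "avg_background".
#' @param background average background level for `avg_background`
#'   (from [extract_features()]).
#' @return numeric matrix.
#' @export
normalize_tile <- function(tile, mode = c("none", "zscore", "zerocenter",
                                          "avg_background"),
                           background = NULL) {
  mode <- match.arg(mode)
  px <- tile_pixels(tile) * 1.0
  switch(mode,
         none = px,
         zscore = {
           s <- sd(px)
           if (!is.finite(s) || s < 1e-12)
             refp_stop("normalization_failure",
                       "z-score normalization of a constant tile")
           (px - mean(px)) / s
         },
         zerocenter = px - mean(px),
         avg_background = {
           if (is.null(background))
             refp_stop("invalid_argument",
                       "avg_background normalization needs a background level")
           px / background
         })
}

#' Center-crop or pass through a tile to the network input size
#' @noRd
fit_input_px <- function(px, input_px = 64) {
  n <- nrow(px)
  if (n == input_px) return(px)
  if (n < input_px)
    refp_stop("invalid_argument", "tile smaller than network input")
  o <- (n - input_px) %/% 2
  px[o + seq_len(input_px), o + seq_len(input_px)]
}

#' Assemble a labeled training set from tiles and a REFP table
#'
#' Labels every tile with `dz = z_um - refp_final` of its (experiment,
#' exposure, fov) combination (positive above the REFP) and removes outlier
#' tiles per acquisition by IQR filtering on the steepest-slope feature.
#'
#' @param tiles list of `bead_tile` objects (with `key` and `bead_id`).
#' @param refp_table data.frame from [estimate_refp()].
#' @param features features table (provides `ss` and `background` per
#'   tile).
#' @param k IQR multiplier for SS outlier removal.
#' @param input_px network input side.
#' @return a `dz_dataset`: list with `x` (n x input_px^2 matrix of flattened
#'   tiles), `y` (dz labels, um), `background`, and `meta`.
#' @export
make_training_set <- function(tiles, refp_table, features, k = 1.5,
                              input_px = 64) {
  if (length(tiles) == 0) refp_stop("invalid_argument", "no tiles")
  refp_key <- key_string(refp_table$experiment, refp_table$exposure_ms,
                         refp_table$fov)
  feat_key <- paste(key_string(features$experiment, features$exposure_ms,
                               features$fov),
                    features$z_um, features$bead_id, sep = "|")
  meta <- lapply(tiles, function(tl) {
    kk <- key_string(tl$key$experiment, tl$key$exposure_ms, tl$key$fov)
    i <- match(kk, refp_key)
    if (is.na(i))
      refp_stop("labeling_failure", "no REFP for combination %s", kk)
    j <- match(paste(kk, tl$key$z_um, tl$bead_id, sep = "|"), feat_key)
    if (is.na(j))
      refp_stop("labeling_failure", "no features row for tile %s bead %s",
                kk, tl$bead_id)
    data.frame(key = kk, z_um = tl$key$z_um, bead_id = tl$bead_id,
               dz = tl$key$z_um - refp_table$refp_final[i],
               ss = features$ss[j], background = features$background[j])
  })
  meta <- do.call(rbind, meta)
  # per-acquisition SS outlier removal
  grp <- paste(meta$key, meta$z_um, sep = "|")
  keep <- logical(nrow(meta))
  for (g in unique(grp)) {
    sel <- grp == g
    keep[sel] <- iqr_filter(meta$ss[sel], k)
  }
  x <- t(vapply(tiles[keep], function(tl)
    as.numeric(fit_input_px(tl$pixels, input_px)),
    numeric(input_px^2)))
  structure(list(x = x, y = meta$dz[keep], background = meta$background[keep],
                 meta = cbind(meta[keep, ], kept = TRUE),
                 n_removed = sum(!keep), input_px = input_px),
            class = "dz_dataset")
}

#' @export
print.dz_dataset <- function(x, ...) {
  cat(sprintf("<dz_dataset> %d tiles (%d removed as SS outliers), dz [%g, %g] um\n",
              nrow(x$x), x$n_removed, min(x$y), max(x$y)))
  invisible(x)
}

cpp_config <- function(config, augmentation) {
  list(initial_learning_rate = config$initial_learning_rate,
       lr_drop_period_epochs = as.integer(config$lr_drop_period_epochs),
       lr_drop_factor = config$lr_drop_factor,
       batch_size = as.integer(config$batch_size),
       validation_frequency_steps =
         as.integer(config$validation_frequency_steps),
       validation_patience = as.integer(config$validation_patience),
       l2_weight_decay = config$l2_weight_decay,
       validation_fraction = config$validation_fraction,
       max_epochs = as.integer(config$max_epochs),
       norm_mode = norm_mode_int(config$normalization_mode),
       c1 = as.integer(config$c1), c2 = as.integer(config$c2),
       hidden = as.integer(config$hidden),
       augment = isTRUE(augmentation$enabled),
       translate_px = augmentation$translate_px,
       rotate_deg = augmentation$rotate_deg,
       scale_lo = augmentation$scale[1], scale_hi = augmentation$scale[2],
       reflection = isTRUE(augmentation$reflection),
       jitter_amplitude = augmentation$jitter_amplitude)
}

#' Train one dZ regression model
#'
#' Trains the reduced-depth residual CNN on a labeled tile dataset with the
#' configured schedule, early stopping on the validation split, and
#' sharpness-preserving augmentation. Deterministic for a fixed
#' `model_seed`.
#'
#' @param dataset a `dz_dataset` from [make_training_set()].
#' @param config a [training_config()].
#' @param model_seed seed for initialization, split, shuffling and
#'   augmentation.
#' @param augmentation an [augmentation_config()].
#' @return a `dz_model`: network weights plus config, seed, training label
#'   range and the validation RMSE trajectory.
#' @export
train_model <- function(dataset, config = training_config(),
                        model_seed = config$seed,
                        augmentation = augmentation_config()) {
  stopifnot(inherits(dataset, "dz_dataset"))
  if (nrow(dataset$x) < config$batch_size)
    refp_stop("invalid_argument", "dataset smaller than one batch")
  res <- .cnn_train_cpp(dataset$x, dataset$y, dataset$background,
                        cpp_config(config, augmentation),
                        as.integer(model_seed))
  structure(list(net = res[c("W", "b", "c1", "c2", "hidden", "g_in",
                             "label_scale")],
                 config = config, augmentation = augmentation,
                 seed = model_seed,
                 label_range = range(dataset$y),
                 norm_mode = config$normalization_mode,
                 log = res$log, best_val_rmse = res$best_val_rmse,
                 epochs_run = res$epochs_run,
                 n_train = res$n_train, n_val = res$n_val),
            class = "dz_model")
}

#' @export
print.dz_model <- function(x, ...) {
  cat(sprintf(
    "<dz_model> seed %s, %d epochs, val RMSE %.2f um, labels [%g, %g] um\n",
    x$seed, x$epochs_run, x$best_val_rmse, x$label_range[1],
    x$label_range[2]))
  invisible(x)
}

#' Tiles argument to prediction matrix
#' @noRd
tiles_to_matrix <- function(tiles, input_px = 64) {
  if (is.matrix(tiles) && ncol(tiles) == input_px^2) return(tiles)
  if (inherits(tiles, "bead_tile")) tiles <- list(tiles)
  if (is.matrix(tiles)) tiles <- list(tiles)
  t(vapply(tiles, function(tl)
    as.numeric(fit_input_px(tile_pixels(tl), input_px)),
    numeric(input_px^2)))
}

#' Predict dZ for bead tiles with one trained model
#'
#' @param object a `dz_model`.
#' @param tiles list of `bead_tile`s / matrices, or an n x 4096 matrix.
#' @param background per-tile background levels (needed for
#'   "avg_background" normalization).
#' @param ... unused.
#' @return numeric vector of per-tile dZ estimates (um).
#' @export
predict.dz_model <- function(object, tiles, background = NULL, ...) {
  x <- tiles_to_matrix(tiles, object$config$network_input_px)
  bg <- background %||% rep(1, nrow(x))
  as.numeric(.cnn_predict_cpp(object$net, x, bg,
                              norm_mode_int(object$norm_mode)))
}

#' Train an ensemble of dZ regression models
#'
#' Trains `config$n_models` networks on the same dataset; member m uses
#' seed `config$seed + m`, so members differ only in initialization, data
#' shuffling and augmentation draws.
#'
#' @inheritParams train_model
#' @return a `dz_ensemble` (list of `dz_model`s).
#' @export
train_ensemble <- function(dataset, config = training_config(),
                           augmentation = augmentation_config()) {
  models <- lapply(seq_len(config$n_models), function(m)
    train_model(dataset, config, model_seed = config$seed + m, augmentation))
  structure(models, class = "dz_ensemble")
}

#' @export
print.dz_ensemble <- function(x, ...) {
  cat(sprintf("<dz_ensemble> %d models, val RMSE %s um\n", length(x),
              paste(sprintf("%.1f", vapply(x, `[[`, 0, "best_val_rmse")),
                    collapse = ", ")))
  invisible(x)
}

#' Two-level ensemble dZ prediction with outlier removal
#'
#' Every model predicts dZ for every bead tile of one acquisition. Per
#' model, bead-level predictions outside the IQR fences are removed and the
#' rest averaged; the final estimate is the mean of the per-model means. If
#' the IQR filter removes every bead for a model (cannot happen with the
#' default fences, but guards custom `k`), that model's mean falls back to
#' the unfiltered average and is flagged.
#'
#' @param models a `dz_ensemble`, or any list of objects with a `predict`
#'   method returning per-tile dZ values.
#' @param tiles tiles of one acquisition (already SS-outlier-filtered).
#' @param background per-tile background levels, if the models need them.
#' @param k IQR multiplier for per-model outlier removal.
#' @return a `dz_prediction`: list with `dz_final`, `per_model_mean`,
#'   `per_bead_per_model` (n_beads x n_models), `model_spread` (sd of the
#'   per-model means) and `flags`.
#' @export
predict_dz <- function(models, tiles, background = NULL, k = 1.5) {
  if (inherits(models, "dz_model")) models <- list(models)
  if (length(models) == 0) refp_stop("invalid_argument", "no models")
  preds <- vapply(models, function(m) {
    p <- predict(m, tiles, background = background)
    as.numeric(p)
  }, numeric(if (is.matrix(tiles)) nrow(tiles)
             else if (inherits(tiles, "bead_tile")) 1L
             else length(tiles)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  flags <- character(0)
  per_model <- apply(preds, 2, function(p) {
    keep <- iqr_filter(p, k)
    if (!any(keep)) {
      flags <<- c(flags, "all_beads_outliers_for_a_model")
      mean(p)
    } else mean(p[keep])
  })
  dz_final <- mean(per_model)
  ranges <- lapply(models, function(m) m$label_range)
  ranges <- ranges[!vapply(ranges, is.null, TRUE)]
  if (length(ranges)) {
    rng <- range(unlist(ranges))
    if (dz_final < rng[1] || dz_final > rng[2])
      flags <- c(flags, "outside_training_range")
  }
  structure(list(dz_final = dz_final, per_model_mean = per_model,
                 per_bead_per_model = preds,
                 model_spread = if (length(per_model) > 1) sd(per_model)
                 else 0,
                 flags = unique(flags)),
            class = "dz_prediction")
}

#' @export
print.dz_prediction <- function(x, ...) {
  cat(sprintf("<dz_prediction> dz_final = %.2f um (%d beads x %d models, spread %.2f)\n",
              x$dz_final, nrow(x$per_bead_per_model),
              ncol(x$per_bead_per_model), x$model_spread))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Save / load a model ensemble
#'
#' Each member is written as a weights file plus a JSON sidecar with the
#' configuration, seed, training label range and validation log.
#'
#' @param models a `dz_ensemble`.
#' @param dir output directory.
#' @return `save_models`: the directory, invisibly. `load_models`: a
#'   `dz_ensemble`.
#' @export
save_models <- function(models, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    refp_stop("io_error", "cannot create %s", dir)
  for (i in seq_along(models)) {
    m <- models[[i]]
    saveRDS(m, file.path(dir, sprintf("model_%02d.rds", i)))
    side <- list(seed = m$seed, label_range = m$label_range,
                 normalization_mode = m$norm_mode,
                 best_val_rmse = m$best_val_rmse,
                 epochs_run = m$epochs_run,
                 config = unclass(m$config),
                 log = m$log)
    jsonlite::write_json(side, file.path(dir, sprintf("model_%02d.json", i)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname save_models
#' @param dir directory written by [save_models()].
#' @export
load_models <- function(dir) {
  files <- sort(list.files(dir, pattern = "^model_\\d+\\.rds$",
                           full.names = TRUE))
  if (length(files) == 0) refp_stop("io_error", "no model files in %s", dir)
  structure(lapply(files, readRDS), class = "dz_ensemble")
}

#' Apply one random sharpness-preserving augmentation to a tile
#'
#' Exposed mainly for testing that augmentation does not alter the feature
#' distribution of tiles.
#'
#' @param tile 64 x 64 tile (`bead_tile` or matrix).
#' @param augmentation an [augmentation_config()].
#' @param seed RNG seed.
#' @return augmented numeric 64 x 64 matrix.
#' @export
augment_tile <- function(tile, augmentation = augmentation_config(),
                         seed = NULL) {
  px <- fit_input_px(tile_pixels(tile), 64)
  with_seed(seed, {
    .augment_tile_cpp(px,
                      isTRUE(augmentation$reflection) && runif(1) < 0.5,
                      runif(1, -1, 1) * augmentation$rotate_deg,
                      runif(1, augmentation$scale[1], augmentation$scale[2]),
                      runif(1, -1, 1) * augmentation$translate_px,
                      runif(1, -1, 1) * augmentation$translate_px,
                      1 + runif(1, -1, 1) * augmentation$jitter_amplitude)
  })
}
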