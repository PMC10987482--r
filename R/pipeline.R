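log_info <- function(stage, ...) {
  kv <- c(...)
  message(sprintf("[%s] %s", stage,
                  paste(names(kv), unname(kv), sep = "=", collapse = " ")))
}

#' Run the simulate / detect / refp / train / predict pipeline
#'
#' Executes the configured stages in order, writing every intermediate
#' artifact (manifest, features CSV, REFP CSV, pooled-profile JSON, model
#' directory, prediction JSON) under `out_dir`. Identical configuration and
#' seeds reproduce identical artifacts. A stage failure stops the run with
#' the stage name; artifacts of completed stages remain on disk.
#'
#' The configuration is a named list (or a YAML file with the same
#' structure) with any of the stage blocks:
#' \describe{
#'   \item{simulate}{arguments to [sweep_spec()] plus optional
#'     `optical` (arguments to [optical_model()]).}
#'   \item{detect}{`manifest` path (defaults to the simulated one) and
#'     optional `tile_size`, `pct`.}
#'   \item{refp}{optional `k` (IQR multiplier).}
#'   \item{train}{arguments to [training_config()] (e.g. `n_models`,
#'     `max_epochs`, `seed`).}
#'   \item{predict}{`manifest` path of acquisitions to predict (defaults to
#'     the simulated one) plus optional `n_beads` limiting beads per
#'     acquisition.}
#' }
#'
#' @param config named list or path to a YAML file.
#' @param out_dir artifact directory.
#' @return named list of artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    refp_stop("io_error", "cannot create %s", out_dir)
  artifacts <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      refp_stop("stage_failure", "stage '%s' failed: %s", name,
                conditionMessage(e))
    })
  }

  manifest <- NULL; manifest_path <- NULL
  if (!is.null(config$simulate)) {
    run_stage("simulate", {
      sim <- config$simulate
      om <- do.call(optical_model, sim$optical %||% list())
      sim$optical <- NULL
      spec <- do.call(sweep_spec, sim)
      img_dir <- file.path(out_dir, "images")
      manifest <- generate_sweep(spec, om, img_dir)
      manifest_path <- file.path(img_dir, "manifest.csv")
      artifacts$manifest <- manifest_path
      log_info("simulate", c(images = nrow(manifest)))
    })
  }

  features <- NULL; tiles <- NULL
  if (!is.null(config$detect)) {
    run_stage("detect", {
      det <- config$detect
      mp <- det$manifest %||% manifest_path
      if (is.null(mp)) refp_stop("invalid_argument",
                                 "detect stage needs a manifest")
      man <- load_manifest(mp)
      fe <- features_for_manifest(man, attr(man, "image_dir"),
                                  keep_tiles = TRUE,
                                  tile_size = det$tile_size %||% 64,
                                  pct = det$pct %||% 1)
      features <- fe$features
      tiles <- fe$tiles
      fp <- file.path(out_dir, "features.csv")
      write.csv(features, fp, row.names = FALSE)
      artifacts$features <- fp
      saveRDS(tiles, file.path(out_dir, "tiles.rds"))
      artifacts$tiles <- file.path(out_dir, "tiles.rds")
      log_info("detect", c(images = nrow(man), beads = nrow(features)))
    })
  }

  refp <- NULL
  if (!is.null(config$refp)) {
    run_stage("refp", {
      if (is.null(features)) {
        fp <- config$refp$features %||% file.path(out_dir, "features.csv")
        features <- read.csv(fp)
      }
      refp <- estimate_refp(features, k = config$refp$k %||% 1.5)
      rp <- file.path(out_dir, "refp.csv")
      write.csv(refp, rp, row.names = FALSE)
      artifacts$refp <- rp
      pj <- file.path(out_dir, "pooled_profiles.json")
      write_pooled_json(attr(refp, "pooled"), pj)
      artifacts$pooled <- pj
      log_info("refp", c(combinations = nrow(refp),
                         refp_mean = sprintf("%.2f", mean(refp$refp_final))))
    })
  }

  models <- NULL
  if (!is.null(config$train)) {
    run_stage("train", {
      if (is.null(tiles) || is.null(refp) || is.null(features))
        refp_stop("invalid_argument",
                  "train stage needs detect and refp stages (or artifacts)")
      cfg <- do.call(training_config, config$train)
      ds <- make_training_set(tiles, refp, features)
      models <- train_ensemble(ds, cfg)
      md <- file.path(out_dir, "models")
      save_models(models, md)
      artifacts$models <- md
      log_info("train", c(tiles = nrow(ds$x), models = length(models)))
    })
  }

  if (!is.null(config$predict)) {
    run_stage("predict", {
      if (is.null(models)) {
        md <- config$predict$models %||% file.path(out_dir, "models")
        if (!dir.exists(md))
          refp_stop("invalid_argument",
                    "predict stage needs trained models (run the train stage or pass predict$models)")
        models <- load_models(md)
      }
      mp <- config$predict$manifest %||% manifest_path
      man <- load_manifest(mp)
      res <- list()
      for (i in seq_len(nrow(man))) {
        row <- man[i, ]
        img <- read_image(file.path(attr(man, "image_dir"), row$path))
        fe <- bead_features(img, as.list(row[c("experiment", "exposure_ms",
                                               "fov", "z_um")]),
                            keep_tiles = TRUE)
        if (nrow(fe$features) == 0) next
        keep <- iqr_filter(fe$features$ss)
        tl <- fe$tiles[keep]
        nb <- config$predict$n_beads %||% length(tl)
        tl <- tl[seq_len(min(nb, length(tl)))]
        pr <- predict_dz(models, tl,
                         background = fe$features$background[keep][
                           seq_len(min(nb, sum(keep)))])
        res[[i]] <- list(experiment = row$experiment,
                         exposure_ms = row$exposure_ms, fov = row$fov,
                         z_um = row$z_um, dz_final = pr$dz_final,
                         per_model_mean = pr$per_model_mean,
                         per_bead_per_model = pr$per_bead_per_model,
                         flags = pr$flags)
      }
      pp <- file.path(out_dir, "predictions.json")
      jsonlite::write_json(res[!vapply(res, is.null, TRUE)], pp,
                           auto_unbox = TRUE, digits = NA)
      artifacts$predictions <- pp
      log_info("predict", c(acquisitions = length(res)))
    })
  }
  artifacts
}
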