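test_that("tile normalization modes match their definitions", {
  set.seed(1)
  tl <- matrix(sample(30:220, 64 * 64, TRUE), 64, 64)
  z <- normalize_tile(tl, "zscore")
  expect_lt(abs(mean(z)), 1e-6)
  expect_equal(sd(z), 1, tolerance = 1e-6)
  expect_equal(normalize_tile(tl, "none"), tl * 1.0)
  zc <- normalize_tile(matrix(42, 64, 64), "zerocenter")
  expect_true(all(zc == 0))
  ab <- normalize_tile(tl, "avg_background", background = 200)
  expect_equal(mean(ab), mean(tl) / 200)
  expect_error(normalize_tile(matrix(7, 64, 64), "zscore"),
               class = "normalization_failure")
  expect_error(normalize_tile(tl, "avg_background"),
               class = "invalid_argument")
})

fake_tile <- function(z, bead_id, key = list(experiment = "e",
                                             exposure_ms = 10, fov = 1),
                      seed = 1) {
  set.seed(seed * 1000 + bead_id + round(z))
  structure(list(pixels = matrix(sample(0:255, 4096, TRUE), 64, 64),
                 nominal_center = c(x = 32, y = 32), offset = c(x = 0, y = 0),
                 saturated_count = 0L,
                 key = c(key, list(z_um = z)), bead_id = bead_id),
            class = "bead_tile")
}

test_that("training sets label tiles as z - REFP and drop SS outliers", {
  refp <- data.frame(experiment = "e", exposure_ms = 10, fov = 1,
                     refp_ss = 1507, refp_ci = 1508, refp_final = 1507.5)
  zs <- c(1500, 1507.5, 1530)
  tiles <- list(); feats <- list()
  for (z in zs) for (b in 1:10) {
    tiles[[length(tiles) + 1]] <- fake_tile(z, b)
    feats[[length(feats) + 1]] <- data.frame(
      experiment = "e", exposure_ms = 10, fov = 1, z_um = z, bead_id = b,
      ss = -0.4 + 0.005 * b + if (b > 8) 5 else 0, # beads 9, 10 are outliers
      ci = 1.5, background = 100, saturated_count = 0L)
  }
  features <- do.call(rbind, feats)
  ds <- make_training_set(tiles, refp, features)
  expect_s3_class(ds, "dz_dataset")
  expect_identical(nrow(ds$x), 24L) # 8 kept per acquisition
  expect_identical(ds$n_removed, 6L)
  expect_setequal(unique(ds$y), zs - 1507.5)
  expect_true(all(abs(ds$y[ds$meta$z_um == 1500] + 7.5) < 1e-9))
  bad <- tiles
  bad[[1]]$key$experiment <- "other"
  expect_error(make_training_set(bad, refp, features),
               class = "labeling_failure")
})

test_that("two-level aggregation equals the analytic mean for random matrices", {
  set.seed(42)
  for (case in 1:60) {
    n_beads <- sample(2:12, 1)
    n_models <- sample(1:6, 1)
    pm <- matrix(rnorm(n_beads * n_models, sd = 20), n_beads, n_models)
    if (case %% 3 == 0) pm[1, ] <- pm[1, ] + 300 # gross outlier bead
    models <- lapply(seq_len(n_models), function(m) mock_model(pm[, m]))
    pr <- predict_dz(models, dummy_tiles(n_beads))
    expect_equal(pr$dz_final, two_level_mean(pm), tolerance = 1e-12)
    expect_equal(dim(pr$per_bead_per_model), c(n_beads, n_models))
  }
  # constant models: the prediction is that constant
  models <- lapply(1:5, function(m) mock_model(4.25))
  pr <- predict_dz(models, dummy_tiles(7))
  expect_identical(pr$dz_final, 4.25)
})

test_that("per-model IQR removal absorbs a grossly mispredicted bead", {
  set.seed(9)
  base <- rnorm(7, sd = 2)
  models <- lapply(1:5, function(m) mock_model(base + rnorm(7, sd = 0.3)))
  clean <- predict_dz(models, dummy_tiles(7))$dz_final
  shifted <- lapply(1:5, function(m) {
    v <- models[[m]]$values
    v[3] <- v[3] + 200
    mock_model(v)
  })
  dirty <- predict_dz(shifted, dummy_tiles(7))$dz_final
  expect_lt(abs(dirty - clean), 1)
})

test_that("predictions outside the training label range are flagged", {
  inside <- mock_model(5, label_range = c(-60, 60))
  outside <- mock_model(95, label_range = c(-60, 60))
  expect_length(predict_dz(list(inside), dummy_tiles(5))$flags, 0)
  expect_identical(predict_dz(list(outside), dummy_tiles(5))$flags,
                   "outside_training_range")
})

test_that("augmentation preserves intensity range and the SS feature distribution", {
  om <- optical_model()
  set.seed(3)
  ss_raw <- c(); ss_aug <- c()
  for (i in 1:12) {
    tl <- render_bead(runif(1, -25, 25), 9, om,
                      center = c(32, 32) + runif(2, -1, 1), seed = i)
    # moderate translation keeps the bead inside the center-search bounds;
    # the property under test is sharpness, not placement
    aug <- augment_tile(tl, augmentation_config(translate_px = 3),
                        seed = 100 + i)
    expect_true(all(aug >= 0 & aug <= 255))
    # optimize the center on both sides so the comparison isolates sharpness
    ss_raw <- c(ss_raw, extract_features(
      profile_sse(tl, optimize_center(tl)$center))$ss)
    ss_aug <- c(ss_aug, extract_features(
      profile_sse(aug, optimize_center(aug)$center))$ss)
  }
  # sharpness-preserving: per-tile SS moves by a few percent at most
  # (bilinear resampling of rotation/scale smooths slightly) and the
  # distribution mean stays put
  rel <- abs(ss_aug - ss_raw) / abs(ss_raw)
  expect_lt(max(rel), 0.12)
  expect_lt(mean(rel), 0.06)
  expect_lt(abs(mean(ss_aug) - mean(ss_raw)) / abs(mean(ss_raw)), 0.10)
})

small_training_run <- function(n_per_level = 24, seed = 7,
                               config = training_config(
                                 n_models = 1, max_epochs = 40,
                                 initial_learning_rate = 1e-3,
                                 c1 = 6, c2 = 12, hidden = 24, seed = 7)) {
  om <- optical_model()
  zs <- seq(-45, 45, 15)
  set.seed(seed)
  tiles <- list(); y <- c()
  for (z in zs) for (i in seq_len(n_per_level)) {
    tiles[[length(tiles) + 1]] <-
      as.numeric(render_bead(z, 12, om, center = c(32, 32) + runif(2, -2, 2),
                             seed = refplane:::mix_seed(seed, z * 10, i)))
    y <- c(y, z)
  }
  x <- do.call(rbind, tiles)
  ds <- structure(list(x = x, y = y, background = rep(102, nrow(x)),
                       meta = NULL, n_removed = 0L, input_px = 64),
                  class = "dz_dataset")
  list(dataset = ds, config = config)
}

test_that("training beats the constant predictor and is seed-deterministic", {
  run <- small_training_run()
  m1 <- train_model(run$dataset, run$config, model_seed = 11)
  # the best constant predictor's RMSE is the label standard deviation
  expect_lt(m1$best_val_rmse, sd(run$dataset$y))
  m2 <- train_model(run$dataset, run$config, model_seed = 11)
  probe <- run$dataset$x[seq(1, 60, 7), ]
  expect_identical(predict(m1, probe), predict(m2, probe))
  m3 <- train_model(run$dataset, run$config, model_seed = 12)
  expect_false(identical(predict(m1, probe), predict(m3, probe)))
})

test_that("ensembles train distinct members and save/load round-trips", {
  run <- small_training_run(
    config = training_config(n_models = 2, max_epochs = 4, c1 = 4, c2 = 8,
                             hidden = 16, seed = 3))
  ens <- train_ensemble(run$dataset, run$config)
  expect_length(ens, 2)
  expect_false(identical(ens[[1]]$net$W[[1]], ens[[2]]$net$W[[1]]))
  expect_identical(ens[[1]]$seed, 4)
  dir <- withr::local_tempdir()
  save_models(ens, dir)
  expect_length(list.files(dir, pattern = "json$"), 2)
  back <- load_models(dir)
  probe <- run$dataset$x[1:5, ]
  expect_identical(predict(back[[1]], probe), predict(ens[[1]], probe))
  pr <- predict_dz(back, probe)
  expect_length(pr$per_model_mean, 2)
  expect_true(is.finite(pr$model_spread))
})
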