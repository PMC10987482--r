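test_that("rendering is deterministic for identical seed and spec", {
  om <- optical_model()
  a <- render_field(12.5, 9, om, n_beads = 5, n_distractors = 2,
                    width = 256, height = 224, seed = 31)
  b <- render_field(12.5, 9, om, n_beads = 5, n_distractors = 2,
                    width = 256, height = 224, seed = 31)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  c <- render_field(12.5, 9, om, n_beads = 5, n_distractors = 2,
                    width = 256, height = 224, seed = 32)
  expect_false(identical(a$image, c$image))
})

test_that("rendered tiles are 8-bit and arguments are validated", {
  tl <- render_bead(0, 12, seed = 1)
  expect_true(is.matrix(tl) && all(tl >= 0 & tl <= 255))
  expect_true(all(tl == round(tl)))
  expect_error(render_bead(0, -3), class = "invalid_argument")
  expect_error(render_bead(0, 12, tile_size = 0), class = "invalid_argument")
  expect_error(render_field(0, 0), class = "invalid_argument")
})

test_that("center intensity peaks and steepest slope bottoms at focus", {
  om <- optical_model(noise_sd = 0)
  dzs <- seq(-30, 30, by = 7.5)
  feats <- lapply(dzs, function(dz) {
    tl <- render_bead(dz, 9, om, center = c(32, 32))
    extract_features(profile_sse(tl, c(32, 32)))
  })
  ci <- vapply(feats, `[[`, 0, "ci")
  ss <- vapply(feats, `[[`, 0, "ss")
  i0 <- which(dzs == 0)
  expect_equal(which.max(ci), i0)
  expect_true(all(ci[i0] > ci[-i0]))
  expect_equal(which.min(ss), i0)
  expect_true(all(ss < 0))
  # unimodal on each side of the focus
  expect_true(all(diff(ci[dzs <= 0]) > 0))
  expect_true(all(diff(ci[dzs >= 0]) < 0))
})

test_that("defocused tiles clearly differ above versus below focus", {
  om <- optical_model(noise_sd = 0)
  up <- render_bead(30, 9, om, center = c(32, 32))
  down <- render_bead(-30, 9, om, center = c(32, 32))
  # the above-focus halo ring makes |dz| and -|dz| distinguishable
  expect_gt(mean(abs(up - down)), 1)
})

test_that("exposure scales background linearly until clipping", {
  om <- optical_model(noise_sd = 0)
  t1 <- render_bead(20, 6, om, center = c(32, 32))
  t2 <- render_bead(20, 12, om, center = c(32, 32))
  corner <- t1[1:10, 1:10] # pure background far from the bead
  expect_equal(mean(t2[1:10, 1:10]) / mean(corner), 2, tolerance = 0.02)
  # saturation: high exposure clips at the sensor maximum
  hot <- render_bead(0, 40, om, center = c(32, 32))
  expect_true(any(hot == 255))
  expect_true(max(hot) == 255)
})

test_that("noise-free centered beads are reflection symmetric", {
  om <- optical_model(noise_sd = 0)
  tl <- render_bead(15, 9, om, tile_size = 63, center = c(31, 31))
  expect_identical(tl, tl[63:1, ])
  expect_identical(tl, tl[, 63:1])
  expect_identical(tl, t(tl))
})

test_that("field ground truth matches the requested bead count", {
  om <- optical_model()
  fr <- render_field(0, 12, om, n_beads = 6, n_distractors = 0,
                     width = 512, height = 448, seed = 5)
  expect_identical(nrow(fr$truth), 6L)
  empty <- render_field(0, 12, om, n_beads = 0, n_distractors = 0,
                        width = 128, height = 128, seed = 5)
  expect_equal(nrow(empty$truth), 0)
  expect_lt(diff(range(empty$image)), 25) # background plus noise only
  expect_error(
    render_field(0, 12, om, n_beads = 40, width = 160, height = 160,
                 seed = 5),
    class = "placement_failure")
})

test_that("generate_sweep writes one image per (z, exposure, fov) with dz labels", {
  spec <- sweep_spec(z_min = 1200, z_max = 1800, z_increment = 7.5,
                     exposures = c(6, 9), n_fov = 2, beads_per_fov = 2,
                     true_refp = 1507.5, seed = 3,
                     image_width = 128, image_height = 112)
  expect_length(spec$z_levels, 81)
  out <- withr::local_tempdir()
  man <- generate_sweep(spec, optical_model(), out)
  expect_identical(nrow(man), 81L * 2L * 2L)
  expect_true(all(file.exists(file.path(out, man$path))))
  row <- man[man$z_um == 1500 & man$exposure_ms == 6 & man$fov == 1, ]
  expect_equal(row$true_dz_um, -7.5) # below the REFP is negative
  # manifest round-trips through the loader
  m2 <- load_manifest(file.path(out, "manifest.csv"))
  expect_equal(nrow(m2), nrow(man))
})

test_that("bead placement is held fixed across a sweep", {
  spec <- sweep_spec(z_min = 1500, z_max = 1515, z_increment = 7.5,
                     exposures = 9, n_fov = 1, beads_per_fov = 3,
                     true_refp = 1507.5, seed = 8,
                     image_width = 160, image_height = 160)
  out <- withr::local_tempdir()
  generate_sweep(spec, optical_model(noise_sd = 0), out)
  imgs <- lapply(list.files(out, pattern = "\\.tif$", full.names = TRUE),
                 read_image)
  # the darkness centroid is set by the bead positions, which must not
  # move while the stage sweeps z
  coms <- t(vapply(imgs, function(im) {
    w <- (255 - im)^2
    c(sum(col(im) * w), sum(row(im) * w)) / sum(w)
  }, numeric(2)))
  expect_lt(max(dist(coms)), 3)
})
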