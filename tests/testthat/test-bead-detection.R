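test_that("percentile threshold marks the darkest pixels", {
  img <- matrix(200L, 50, 50)
  img[10:15, 10:15] <- 20L # 36 px: more than the 1% interpolation index
  cl <- threshold_percentile(img, pct = 1)
  expect_equal(cl$threshold, 20)
  expect_equal(cl$n_clusters, 1)
  # constant image: mask covers everything, one degenerate cluster
  flat <- matrix(100L, 40, 40)
  clf <- threshold_percentile(flat, pct = 1)
  expect_equal(clf$threshold, 100)
  expect_equal(clf$n_clusters, 1)
  expect_true(all(clf$labels == 1))
  det <- filter_clusters(clf, flat)
  expect_false(any(det$accepted)) # rejected downstream
  # pct = 0 with a unique minimum: a single one-pixel cluster
  img0 <- matrix(100L, 30, 30)
  img0[7, 9] <- 1L
  cl0 <- threshold_percentile(img0, pct = 0)
  expect_equal(sum(cl0$labels > 0), 1)
  expect_error(threshold_percentile(matrix(numeric(0), 0, 0)),
               class = "invalid_argument")
})

test_that("clusters are 8-connected", {
  img <- matrix(200L, 20, 20)
  img[cbind(c(5, 6, 7), c(5, 6, 7))] <- 10L # diagonal chain
  cl <- threshold_percentile(img, pct = 2)
  expect_equal(cl$n_clusters, 1)
})

test_that("perimeter estimator calibrates: disks pass 0.9, compact and elongated shapes fail", {
  for (r in c(8, 9.5, 11, 14)) {
    img <- shape_image(80, 80, shape = "disk", cx = 40, cy = 40, r = r)
    det <- detect_beads(img, pct = 2, min_area = 10)
    disk <- det[which.max(det$area), ]
    expect_gt(disk$circularity, 0.9)
    expect_lt(disk$circularity, 1.12)
    expect_equal(disk$area, pi * r^2, tolerance = 0.08)
    expect_equal(disk$x, 40, tolerance = 0.1)
    expect_equal(disk$y, 40, tolerance = 0.1)
  }
  sq <- shape_image(80, 80, shape = "square", cx = 40, cy = 40, side = 20)
  det <- detect_beads(sq, pct = 2, min_area = 10)
  expect_lt(det$circularity[which.max(det$area)], 0.9)
  expect_identical(det$reject_reason[which.max(det$area)], "circularity")
  el <- shape_image(80, 80, shape = "ellipse", cx = 40, cy = 40, a = 15, b = 4)
  det <- detect_beads(el, pct = 2, min_area = 10)
  expect_lt(det$circularity[which.max(det$area)], 0.9)
})

test_that("area filter boundary sits at 180 pixels", {
  img <- matrix(200L, 60, 120)
  img[10 + seq_len(10), 10 + seq_len(18)] <- 20L   # 180 px block
  img[40 + seq_len(10), 80 + seq_len(17)] <- 20L   # 170 px block
  # pct chosen so the interpolated index falls inside the 350 dark pixels
  cl <- threshold_percentile(img, pct = 4)
  det <- filter_clusters(cl, img, min_circularity = 0, min_contrast = 0)
  det <- det[order(-det$area), ]
  expect_equal(det$area[1:2], c(180, 170))
  expect_true(is.na(det$reject_reason[1]))
  expect_identical(det$reject_reason[2], "size")
})

test_that("accepted detections satisfy all filters and rejects name the first failure", {
  om <- optical_model()
  fr <- render_field(10, 12, om, n_beads = 7, n_distractors = 3, seed = 21)
  det <- detect_beads(fr$image)
  acc <- det[det$accepted, ]
  expect_true(all(acc$area >= 180 & acc$circularity >= 0.9 &
                    acc$contrast > 0.1))
  rej <- det[!det$accepted, ]
  expect_true(all(rej$reject_reason %in% c("size", "circularity", "contrast")))
  # filters are conjunctive: reordering cannot change the accepted set
  bad <- with(det, area < 180 | circularity < 0.9 | contrast <= 0.1)
  expect_identical(det$accepted, !bad)
})

test_that("exactly k beads are accepted among elongated distractors", {
  om <- optical_model()
  for (k in c(0, 4, 9, 15, 20)) {
    fr <- render_field(-8, 12, om, n_beads = k, n_distractors = 3,
                       width = 1280, height = 1024, seed = 100 + k)
    det <- detect_beads(fr$image)
    expect_identical(sum(det$accepted), as.integer(k))
    acc <- det[det$accepted, , drop = FALSE]
    if (k > 0) {
      d <- vapply(seq_len(nrow(acc)), function(i)
        min(sqrt((fr$truth$x - acc$x[i])^2 + (fr$truth$y - acc$y[i])^2)), 0)
      expect_lt(max(d), 2)
    }
  }
})

test_that("crop_tile centers, shifts at borders and counts saturation", {
  img <- matrix(50L, 200, 300)
  img[96:104, 146:154] <- 10L
  tl <- crop_tile(img, c(149.6, 99.7), 64)
  expect_identical(dim(tl$pixels), c(64L, 64L))
  expect_equal(tl$nominal_center[["x"]], 31.6)
  expect_equal(tl$nominal_center[["y"]], 31.7)
  # window shifted inward near the border: bead sits off the tile center
  tl2 <- crop_tile(img, c(10, 99.7), 64)
  expect_identical(tl2$offset[["x"]], 0)
  expect_equal(tl2$nominal_center[["x"]], 10)
  expect_equal(abs(tl2$nominal_center[["x"]] - 32), 22)
  img[1:3, 151] <- 255L
  expect_identical(crop_tile(img, c(150, 30), 64)$saturated_count, 3L)
  expect_error(crop_tile(img, c(500, 10), 64), class = "invalid_argument")
  expect_error(crop_tile(matrix(0L, 32, 32), c(10, 10), 64),
               class = "invalid_argument")
})
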