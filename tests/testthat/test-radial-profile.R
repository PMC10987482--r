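test_that("profile sse is near zero at the true center and grows off it", {
  om <- optical_model(noise_sd = 0)
  tl <- render_bead(5, 9, om, center = c(32, 32))
  at_truth <- profile_sse(tl, c(32, 32))
  off <- profile_sse(tl, c(32.5, 32))
  expect_lt(at_truth$sse / at_truth$n, 0.5)
  expect_gt(off$sse, at_truth$sse)
  # the dedicated optimization objective agrees on the ordering
  lam <- optimize_center(tl, c(32, 32))$lambda
  expect_gt(center_objective(tl, c(32.5, 32), lambda = lam),
            center_objective(tl, c(32, 32), lambda = lam))
})

test_that("constant tiles give a flat spline with trivial features", {
  tl <- matrix(200, 64, 64)
  fit <- profile_sse(tl, c(32, 32))
  expect_lt(fit$sse, 1e-6)
  expect_equal(predict(fit, c(1, 10, 30)), rep(200, 3), tolerance = 1e-6)
  fe <- extract_features(fit)
  expect_equal(fe$background, 200, tolerance = 1e-6)
  expect_equal(fe$ci, 1, tolerance = 1e-6)
  expect_equal(fe$ss, 0, tolerance = 1e-6)
})

test_that("spline fit agrees with stats::smooth.spline on a bead scatter", {
  om <- optical_model()
  tl <- render_bead(-10, 12, om, center = c(32, 32), seed = 4)
  fit <- profile_sse(tl, c(32, 32))
  ref <- smooth.spline(fit$r, fit$intensity)
  grid <- seq(1, 40, by = 0.5)
  mine <- predict(fit, grid)
  theirs <- predict(ref, grid)$y
  # two independent cubic smoothing spline implementations, same scatter
  expect_lt(max(abs(mine - theirs)) / diff(range(theirs)), 0.03)
})

test_that("center optimization recovers sub-pixel truth, including off-center beads", {
  om <- optical_model(noise_sd = 0)
  cases <- list(c(32.4, 31.7), c(32.0, 32.0), c(27.0, 33.5))
  for (truth in cases) {
    tl <- render_bead(0, 9, om, center = truth)
    oc <- optimize_center(tl, c(32, 32))
    err <- sqrt(sum((oc$center - truth)^2))
    expect_lt(err, 0.25)
  }
  # 5 px off tile center: far from the midpoint, near the truth
  truth <- c(27.0, 33.5)
  tl <- render_bead(0, 9, om, center = truth)
  oc <- optimize_center(tl, c(32, 32))
  expect_gt(sqrt(sum((oc$center - c(32, 32))^2)), 4.5)
})

test_that("optimizer matches a 0.05 px brute-force grid argmin", {
  om <- optical_model()
  set.seed(10)
  for (i in 1:3) {
    truth <- c(32, 32) + runif(2, -0.6, 0.6)
    tl <- render_bead(runif(1, -25, 25), 12, om, center = truth, seed = i)
    oc <- optimize_center(tl, c(32, 32))
    g <- seq(-0.6, 0.6, by = 0.05)
    best <- c(NA, NA); bv <- Inf
    for (dx in g) for (dy in g) {
      p <- truth + c(dx, dy) # oracle grid spans the known neighbourhood
      v <- center_objective(tl, p, lambda = oc$lambda)
      if (v < bv) { bv <- v; best <- p }
    }
    expect_lt(sqrt(sum((oc$center - best)^2)), 0.1)
  }
})

test_that("SS and CI are invariant to exposure scaling without saturation", {
  om <- optical_model()
  set.seed(2)
  for (i in 1:5) {
    tl <- render_bead(runif(1, -20, 20), 6, om, center = c(32, 32), seed = i)
    for (fac in c(0.5, 1.5)) {
      scaled <- round(tl * fac) # stays below 255 at this exposure
      f1 <- extract_features(profile_sse(tl, c(32, 32)))
      f2 <- extract_features(profile_sse(scaled, c(32, 32)))
      expect_lt(abs(f2$ss - f1$ss) / abs(f1$ss), 0.01)
      expect_lt(abs(f2$ci - f1$ci) / f1$ci, 0.01)
      expect_equal(f2$background / f1$background, fac, tolerance = 0.01)
    }
  }
})

test_that("defocus weakens both features and center optimization raises CI", {
  om <- optical_model(noise_sd = 0)
  focus <- extract_features(profile_sse(render_bead(0, 9, om,
                                                    center = c(32, 32)),
                                        c(32, 32)))
  blur <- extract_features(profile_sse(render_bead(35, 9, om,
                                                   center = c(32, 32)),
                                       c(32, 32)))
  expect_gt(abs(focus$ss), abs(blur$ss))
  expect_gt(focus$ci, blur$ci)
  # off-center bead: optimized-center profile has the brighter center
  truth <- c(29.3, 34.6)
  tl <- render_bead(0, 9, om, center = truth)
  naive <- extract_features(profile_sse(tl, c(32, 32)))
  oc <- optimize_center(tl, c(32, 32))
  opt <- extract_features(profile_sse(tl, oc$center))
  expect_gt(opt$ci, naive$ci)
})

test_that("background window shrinks (with a flag) when the scatter is short", {
  om <- optical_model(noise_sd = 0)
  tl <- render_bead(0, 9, om, center = c(32, 32))
  fit <- profile_sse(tl, c(32, 32), max_radius = 30)
  fe <- extract_features(fit)
  expect_true(fe$bg_window_shrunk)
  expect_gt(fe$background, 0)
  full <- extract_features(profile_sse(tl, c(32, 32)))
  expect_false(full$bg_window_shrunk)
  expect_equal(fe$ci, full$ci, tolerance = 0.05)
})

test_that("degenerate profile inputs raise classed errors", {
  tl <- matrix(100, 64, 64)
  expect_error(profile_sse(tl, c(200, 10)), class = "invalid_argument")
  expect_error(extract_features(profile_sse(tl, c(32, 32), max_radius = 15)),
               class = "feature_failure")
  dark <- matrix(0, 64, 64)
  expect_error(extract_features(profile_sse(dark, c(32, 32))),
               class = "feature_failure")
})
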