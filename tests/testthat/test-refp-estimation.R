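test_that("iqr_filter uses interpolated quartiles and small-n pass-through", {
  keep <- iqr_filter(c(1, 2, 3, 4, 100))
  expect_identical(keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(iqr_filter(rep(7, 10))))
  expect_true(all(iqr_filter(c(1, 50, 1e6)))) # < 4 values: keep everything
  expect_error(iqr_filter(numeric(0)), class = "invalid_argument")
  # property: kept values always lie inside the fences
  set.seed(5)
  for (i in 1:20) {
    v <- rnorm(30) + c(rep(0, 28), 50, -50)
    keep <- iqr_filter(v, k = 1.5)
    q <- quantile(v, c(.25, .75), type = 7, names = FALSE)
    fence <- c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q))
    expect_true(all(v[keep] >= fence[1] & v[keep] <= fence[2]))
    expect_true(all(v[!keep] < fence[1] | v[!keep] > fence[2]))
  }
})

make_features <- function(zs, beads, key = list(experiment = "e",
                                                exposure_ms = 10, fov = 1),
                          sat = function(z, b) 0L) {
  do.call(rbind, lapply(zs, function(z)
    data.frame(experiment = key$experiment, exposure_ms = key$exposure_ms,
               fov = key$fov, z_um = z, bead_id = seq_len(beads),
               x = 0, y = 0,
               ss = -0.4 * exp(-(z - 1500)^2 / 800) - 0.1,
               ci = 1 + exp(-(z - 1500)^2 / 800),
               background = 100,
               saturated_count = vapply(seq_len(beads),
                                        function(b) sat(z, b), 0L))))
}

test_that("sweep curves take medians of IQR-kept beads and flag saturated medians", {
  zs <- seq(1470, 1530, 7.5)
  fe <- make_features(zs, beads = 7)
  # inject one gross outlier per z for each feature
  fe$ss[fe$bead_id == 3] <- fe$ss[fe$bead_id == 3] + 50
  fe$ci[fe$bead_id == 5] <- fe$ci[fe$bead_id == 5] - 40
  cv <- build_sweep_curve(fe)[[1]]
  clean <- make_features(zs, beads = 7)
  ccv <- build_sweep_curve(clean)[[1]]
  expect_equal(cv$points$median_ss, ccv$points$median_ss, tolerance = 1e-9)
  expect_equal(cv$points$median_ci, ccv$points$median_ci, tolerance = 1e-9)
  expect_true(all(cv$points$n_kept_ss == 6))
  # even bead count: median bead saturation is the OR of the two middle beads
  fe6 <- make_features(1500 + c(0, 7.5, 15), beads = 6)
  fe6$ci <- rep(1:6, 3)                 # ordered: middle beads are 3 and 4
  fe6$saturated_count <- ifelse(fe6$bead_id == 4, 2L, 0L)
  cv6 <- build_sweep_curve(fe6, min_z_levels = 3)[[1]]
  expect_equal(cv6$points$median_ci, rep(3.5, 3))
  expect_true(all(cv6$points$sat_ci))
  fe6$saturated_count <- ifelse(fe6$bead_id == 6, 2L, 0L) # not a middle bead
  cv6b <- build_sweep_curve(fe6, min_z_levels = 3)[[1]]
  expect_false(any(cv6b$points$sat_ci))
  expect_error(build_sweep_curve(make_features(c(1500, 1510), beads = 4)),
               class = "curve_failure")
})

test_that("alignment recovers identity, constructed shift/scale, and composes", {
  zs <- seq(1400, 1600, 7.5)
  a <- analytic_curve(zs, peak_z = 1500)
  self <- align_curves(a, a, "ci")
  expect_lt(abs(self$shift_um), 0.5)
  expect_equal(self$scale, 1, tolerance = 0.01)
  # shifted + scaled copy: fixed(z) = 1.2 * moving(z - 30)
  b <- analytic_curve(zs, peak_z = 1530, scale = 1.2, exposure_ms = 20)
  al <- align_curves(a, b, "ci")
  expect_equal(al$shift_um, 30, tolerance = 0.5)
  expect_equal(al$scale, 1.2, tolerance = 0.01)
  al_ss <- align_curves(a, b, "ss")
  expect_equal(al_ss$shift_um, 30, tolerance = 0.5)
  # composition: shift(a->c) ~ shift(a->b) + shift(b->c)
  cc <- analytic_curve(zs, peak_z = 1480, scale = 0.9, exposure_ms = 30)
  s_ab <- align_curves(a, b, "ci")$shift_um
  s_bc <- align_curves(b, cc, "ci")$shift_um
  s_ac <- align_curves(a, cc, "ci")$shift_um
  expect_equal(s_ab + s_bc, s_ac, tolerance = 1)
})

test_that("saturated points are excluded yet alignment stays precise", {
  zs <- seq(1400, 1600, 7.5)
  clean <- analytic_curve(zs, peak_z = 1520)
  sat <- abs(zs - 1520) < 12 # clip the peak region
  satc <- analytic_curve(zs, peak_z = 1520, saturated = sat)
  satc$points$median_ci[sat] <- 1.2 # corrupted where saturated
  ref <- analytic_curve(zs, peak_z = 1500, exposure_ms = 5)
  al_clean <- align_curves(ref, clean, "ci")
  al_sat <- align_curves(ref, satc, "ci")
  expect_lt(abs(al_sat$shift_um - al_clean$shift_um), 7.5)
  expect_error(align_curves(ref, analytic_curve(zs, 1500,
                                                saturated = rep(TRUE,
                                                                length(zs))),
                            "ci"),
               class = "alignment_failure")
})

test_that("pooled profiles reproduce the template and per-curve transforms", {
  zs <- seq(1400, 1600, 7.5)
  shifts <- c(0, 12, -18, 25, 7, -30)
  scales <- c(1, 1.15, 0.9, 1.3, 0.8, 1.05)
  curves <- lapply(seq_along(shifts), function(i)
    analytic_curve(zs, peak_z = 1500 + shifts[i], scale = scales[i],
                   exposure_ms = i))
  names(curves) <- paste0("a|", seq_along(curves), "|1")
  pp <- build_pooled_profile(curves, "ci", reference_key = "a|1|1")
  expect_s3_class(pp, "pooled_profile")
  expect_identical(pp$n_curves, 6L)
  rec <- pp$alignments$shift_um[match(paste0("a|", 1:6, "|1"),
                                      pp$alignments$key)]
  # a curve peaked above the reference aligns with a negative shift:
  # reference(z) = scale * curve(z - shift)
  expect_equal(rec, -shifts, tolerance = 0.5)
  # template shape: pooled peak at the reference's peak
  zg <- seq(1450, 1550, 0.1)
  expect_equal(zg[which.max(predict(pp, zg))], 1500, tolerance = 1)
  # single curve: pooled profile is that curve's own spline
  pp1 <- build_pooled_profile(curves[1], "ci")
  expect_equal(pp1$alignments$shift_um, 0)
  expect_equal(pp1$alignments$scale, 1)
})

test_that("feature-specific REFP finds extrema and flags boundaries", {
  zs <- seq(1400, 1600, 7.5)
  curves <- lapply(1:3, function(i)
    analytic_curve(zs, peak_z = 1512, exposure_ms = i * 10))
  names(curves) <- paste0("a|", 1:3 * 10, "|1")
  for (feat in c("ci", "ss")) {
    pp <- build_pooled_profile(curves, feat)
    fr <- feature_refp(pp, curves[[2]])
    expect_equal(fr$refp_um, 1512, tolerance = 1)
    expect_false(fr$boundary_warning)
  }
  # peak outside the sweep: extremum pinned to the boundary and flagged
  edge <- lapply(1:3, function(i)
    analytic_curve(zs, peak_z = 1650, exposure_ms = i * 10))
  names(edge) <- paste0("a|", 1:3 * 10, "|1")
  ppe <- build_pooled_profile(edge, "ci")
  fre <- feature_refp(ppe, edge[[1]])
  expect_true(fre$boundary_warning)
})

test_that("final REFP is the exact mean of the feature-specific estimates", {
  expect_identical(compute_refp(1500, 1515), 1507.5)
  expect_identical(compute_refp(1507.5, 1507.5), 1507.5)
  expect_identical(compute_refp(1380, 1620), 1500)
  expect_error(compute_refp(NA_real_, 1500), class = "invalid_argument")
})

test_that("estimate_refp is equivariant to a constant nominal-Z offset", {
  zs <- seq(1450, 1550, 7.5)
  fe <- do.call(rbind, lapply(c(10, 20), function(e) {
    f <- make_features(zs, beads = 6,
                       key = list(experiment = "e", exposure_ms = e, fov = 1))
    set.seed(e)
    f$ci <- f$ci + rnorm(nrow(f), sd = 0.01)
    f$ss <- f$ss + rnorm(nrow(f), sd = 0.005)
    f
  }))
  r1 <- estimate_refp(fe)
  fe2 <- fe
  fe2$z_um <- fe2$z_um + 500
  r2 <- estimate_refp(fe2)
  expect_equal(r2$refp_final, r1$refp_final + 500, tolerance = 1e-6)
  expect_equal(r1$refp_final, (r1$refp_ss + r1$refp_ci) / 2)
})
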