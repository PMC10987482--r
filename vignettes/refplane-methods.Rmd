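---
title: "Benchmarking a brightfield Z axis with reference beads: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking a brightfield Z axis with reference beads: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Image-based cell assays need images acquired at a consistent focal plane,
but the nominal Z reported by a microscope stage is not a reliable anchor:
slide thickness, stage drift and instrument differences move the plane of
best focus by tens of micrometers. `refplane` implements a bead-based
benchmark for the Z axis. Polystyrene microspheres mixed into the sample
act as a stable reference material: the package locates the *reference
effective focal plane* (REFP) — the Z at which the beads are most in
focus — from a calibration Z sweep, and then estimates, from a **single**
acquisition, the signed distance dZ of that acquisition from the REFP
(positive above, negative below). The error target throughout is the
mechanical repeatability of the Z actuator, ±7.5 µm.

The pipeline has two halves:

1. **REFP definition** (calibration): detect beads, fit a cubic smoothing
   spline to pixel intensity versus distance from each bead's optimized
   center, extract two background-normalized features — steepest slope
   (SS, the spline-derivative value farthest from zero; most negative at
   focus) and center intensity (CI, the spline value 1 px from the center;
   maximal at focus) — build per-(experiment, exposure, FOV) median
   feature curves over the sweep, pool them into a template profile, and
   define the REFP per combination as `(REFP_SS + REFP_CI)/2`.
2. **dZ regression** (single image): train an ensemble of small
   convolutional regression networks on 64 px bead tiles labeled with
   `z − REFP`, and aggregate predictions per acquisition in two levels
   (IQR-filtered mean over beads per model, then mean over models).

## Synthetic data: what it emulates and what it does not

Everything is validated against a synthetic bead-field generator with
known ground truth (`optical_model()`, `render_field()`,
`generate_sweep()`). A bead is a dark annular body (inner radius 2.5 px to
the bead radius 9.5 px, soft sigmoid edges) on an exposure-proportional
background, with a bright Gaussian center (sigma 2.5 px, amplitude 1.2×
background at focus). Defocus applies an anti-aliased disk blur of radius
`defocus_blur_rate·|dz|` to the field; the center peak instead receives an
analytically equivalent Gaussian defocus added after the blur pass, so
that center intensity varies smoothly in dz and is strictly maximal at
dz = 0 (an integer-raster disk kernel would be the identity for radii
below half a pixel and flatten the CI curve near focus). Above focus, a
faint bright halo ring develops outside the rim (amplitude 0.4×background,
switched on over ~12 µm), and the blur rate is 20% larger above than below
focus. These two asymmetries matter: with a sign-symmetric optical model,
tiles at +dz and −dz would be identical and no single-image method could
recover the sign of dZ. Real brightfield beads are visibly different above
versus below focus, which is exactly what the regression network exploits.

Noise is additive Gaussian (sd 2 counts) followed by rounding and clipping
to 8 bits; saturation is produced naturally by raising exposure. With the
default exposures (6, 12, 15 ms; background 85 counts at 10 ms) only the
top exposure saturates, and only near focus — this exercises the
saturated-median exclusion path of the REFP estimation without destroying
whole curves. Amplitudes were chosen once so that beads remain detectable
over the ±60 µm study range and are statements about plausibility, not
about any particular instrument. The generator does **not** simulate cells
or debris beyond simple elongated dark distractors, physically rigorous
point-spread functions, spatial illumination gradients, or camera gain
nonlinearity; passing tests therefore demonstrate the correctness and
internal consistency of the pipeline, not instrument-level accuracy on
real data.

## Bead detection

Pixels at or below the image's 1st percentile (linear-interpolation
percentile) are grouped into 8-connected clusters; a cluster is accepted
as a bead when (a) its area is at least 180 px, (b) its circularity
`4π·area/perimeter²` is at least 0.9, and (c) the sd/mean of the
intensities in its bounding box dilated by one bead diameter exceeds 0.1.
Two implementation choices deserve note. The bright bead center rises
above the dark-pixel threshold and punches a hole in the mask; interior
holes are filled before the area and shape filters so that the measured
area corresponds to the physical bead. And the perimeter estimator is the
convex-hull length of a 3×3-majority-smoothed copy of the filled cluster,
plus π to correct the half-pixel inset of a boundary through pixel
centers. Chain-code estimators systematically inflate the perimeter of
noise-ragged threshold boundaries (a defocused bead's boundary crosses a
shallow intensity ramp, where read noise displaces the contour pixel by
pixel), pushing true disks below the 0.9 threshold; the hull of a lightly
smoothed mask is robust to this while still failing squares (≈0.8) and
elongated debris (≈0.6). A calibration test asserts that rasterized disks
of radius ≥ 8 px score above 0.9. Note the hull is a correct outline
estimator only for convex objects — beads and the ellipsoidal distractors
are convex; strongly concave debris would be scored too favourably and
must rely on the other filters.

## Radial profiles, center optimization, and features

For a candidate center, every tile pixel within the scatter radius
contributes one (distance, intensity) point — distances are never binned —
and a cubic smoothing spline is fit to the scatter. The spline is a
penalized cubic B-spline (uniform knots, exact integrated-squared-second-
derivative penalty) solved by banded normal equations in C++, with the
penalty weight chosen by generalized cross-validation; a unit test checks
its fitted values against `stats::smooth.spline` on the same scatter. The
bead center is then the continuous (x, y) minimizing the mean squared
spline residual over a 14 px scatter radius (mean rather than sum because
the scatter size changes near tile edges; the smoothing weight is frozen
at its GCV value from the initial center so the objective surface does not
move under the optimizer). The search is a 5×5 coarse grid (the objective
has a spurious mirror-side minimum when the bead is several pixels
off-center) followed by a Nelder–Mead simplex with a small-simplex
restart; tests verify agreement within 0.1 px with a brute-force 0.05 px
grid on the same objective, and recovery within 0.25 px for beads 5 px off
the tile center.

Features come from a full-radius GCV fit: background = mean spline value
over 20–40 px (the window shrinks, flagged, if the scatter is shorter); SS
= the signed derivative extremum over 3–15 px (the rim region) divided by
background; CI = spline(1 px)/background. CI is evaluated at 1 px, not 0,
because the spline extrapolates toward r = 0 where no pixel can sit closer
than the sub-pixel center offset. Both features are scale-free: a ×1.5
exposure change moves them by less than 1% in the absence of saturation.

## From curves to the REFP

Per (experiment, exposure, FOV, Z), bead-level SS and CI are IQR-filtered
(k = 1.5, two-sided, type-7 quartiles — the example `[1,2,3,4,100]` keeps
`1:4`) and the median of the kept beads is recorded; the point is flagged
saturated when the median bead image — both middle beads for an even
count, a conservative OR — contains a saturated pixel. Saturated points
are excluded from every subsequent fit, matching the treatment of clipped
feature values near focus at high exposure.

Curves are aligned by an additive shift in Z and a multiplicative scale in
feature value: a grid search over shifts at a quarter z-increment (the
optimal scale is closed-form at each shift) followed by 1-D refinement.
The reference combination for pooling is the curve with the most
unsaturated points (ties: lowest exposure). One cubic smoothing spline is
fit to the union of aligned points; its knot count is capped at the number
of sweep Z levels, because aligned curves cluster their abscissae within a
fraction of the increment and GCV on such near-duplicates undersmooths,
leaving oscillations that a fine-grid extremum search would latch onto.
The pooled profile is then fitted back to each curve (shift + scale,
saturated points excluded) and the feature-specific REFP is the argmin
(SS) or argmax (CI) of the fitted profile on a z-increment/100 grid across
the sweep range, with a boundary flag when the extremum pins to an end.
`refp_final` is exactly the mean of the two feature REFPs. On ten noisy
synthetic sweeps (3 exposures × 2 FOV × 8 beads, 7.5 µm increment) every
combination recovers the true plane within 7.5 µm; noise-free, within half
an increment.

## The dZ regression network

No deep-learning framework is assumed: the package ships a small residual
convolutional regression network implemented directly in RcppArmadillo
(im2col convolutions as single-GEMM batches, Adam, MSE loss). The default
backbone is two residual blocks over 12 and 24 channels behind a 3×3 stem
and 2× average pools, with a 48-unit dense head — about 20k parameters,
sized so that a three-member ensemble trains in minutes on one CPU. The
64 px tile enters through a 2× average-pool stem (a full-resolution
central-crop stem is available as an option; at this problem's noise level
it performed equivalently). Two data-dependent conditioning constants are
fixed at initialization and stored with the model: an input gain that
scales tiles to unit standard deviation, and a label scale that maps dZ to
roughly ±1 for the loss. Neither is a per-image normalization: the input
gain is one global constant, so exposure information is preserved, and
`normalization_mode = "none"` remains the default (per-image z-score,
zero-centering and background division are implemented and selectable).

All training hyperparameters default to the values selected by
validation-RMSE optimization for this task: initial learning rate 1e-4 dropped
by 0.9 every 15 epochs, batch 32, Adam, validation every 2000 steps on a
20% split with patience 10, L2 weight decay 5e-4, ensemble of 10.
Augmentation is strictly sharpness-preserving: translation ±5 px, rotation
±5°, reflection, ±5% intensity jitter, scale 0.95–1.05 (bilinear,
reflected borders); nothing that alters blur, since blur is the signal. A
test verifies that augmentation leaves the SS feature distribution within
5% of the unaugmented mean.

One scale-dependent adjustment is made for the desk-scale studies, and
only there. At ~2,000 training tiles an epoch is ~50 Adam steps, two
orders of magnitude fewer than at full scale, and with the 1e-4 learning
rate the validation RMSE plateaus near 14 µm however long one trains
(confirmed insensitive to augmentation, input stem and image noise);
raising the initial rate to 1e-3 reaches ~3 µm within 60 epochs. The
scaled-down benchmark (`benchmark_dz_prediction()`) therefore trains with
`initial_learning_rate = 1e-3` and `max_epochs = 60`, keeping every other
hyperparameter at its default. This was decided from validation
trajectories alone; it compensates the smaller step budget, not any test
outcome.

## Two-level prediction aggregation

At inference, beads are first filtered by IQR on their SS feature (the
tile-quality gate), each ensemble member predicts dZ for each remaining
bead, per-model bead outliers are removed by the same IQR rule, the
surviving predictions are averaged per model, and the per-model means are
averaged into `dz_final`. The algebra is unit-tested against an
independent re-implementation on random prediction matrices, without any
trained network. Predictions outside the training label range are flagged
(the network extrapolates poorly outside the dZ range it saw, so a sweep
acquired around a very different focal plane should be retrained, not
extrapolated).

At desk scale (three members, ~2,000 tiles, six beads per acquisition,
held-out sweep inside the training dZ range with an off-grid true focal
plane), the ensemble predicts within 7.5 µm for well over nine in ten
acquisitions; the exact percentages for a given seed are computed by
`scripts/acceptance.R` and by the corresponding test, never quoted
statically here.

## Numerical and policy choices, in brief

- Coordinates are 0-based, (x, y) = (column, row), pixel centers on
  integers.
- Percentiles and quartiles are type-7 (linear interpolation) throughout.
- Degenerate inputs: constant images threshold to a single whole-image
  cluster that the shape filters reject; constant tiles yield a flat
  spline with SS = 0, CI = 1; z-score normalization of a constant tile is
  an error, not a silent zero.
- The curve-level and pooled-profile fits use `stats::smooth.spline`; the
  per-bead fits use the package's own C++ smoothing spline for speed (the
  center optimization evaluates it ~100 times per bead).
- All randomness flows from explicit seeds; sweep generation fixes bead
  placement per FOV (the sample does not move during a sweep) while noise
  is redrawn per image. Ensemble member m trains with `seed + m`.
- Sweep sizes in the shipped studies (ranges ±37.5 to ±60 µm at 7.5 µm
  increments, 2–5 FOVs, 8 beads per FOV, three exposures) were chosen as
  the smallest sets that exercise pooling across exposures and FOVs with
  saturation present; they are stated in `benchmark_refp_recovery()` and
  `benchmark_dz_prediction()` defaults.

## Known limitations

- The REFP is only defined if beads share a focal plane; samples with
  beads at substantially different depths violate the method's premise.
- The hull-based circularity is permissive toward concave debris.
- The regression network must be retrained per instrument (and per
  optical-model parameterization of the generator); the pooled profile is
  likewise refit per dataset and feature.
- Predictions for acquisitions outside the training dZ range are flagged
  rather than corrected.
- The synthetic generator's realism limits what green tests imply about
  any physical instrument; it is a correctness harness, not a camera
  model.
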