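#' Optical model for synthetic bead fields
#'
#' Parameterizes the appearance of a reference microsphere bead in a
#' brightfield image as a function of exposure and of the signed distance dZ
#' from the true focal plane. A bead is rendered as a dark annular body
#' (from `rim_inner_px` out to `bead_radius_px`, with soft sigmoid edges)
#' with a bright Gaussian center whose amplitude peaks exactly at focus.
#' Defocus is modelled by an anti-aliased disk blur of radius
#' `defocus_blur_rate * |dz|` applied to the whole field; the center peak
#' receives an analytically equivalent Gaussian defocus so that center
#' intensity varies smoothly (and is strictly maximal) at dz = 0. Above
#' focus a faint bright halo ring develops outside the bead rim
#' (`halo_gain`, switched on over `focus_sharpness_scale` micrometers);
#' together with a mildly asymmetric blur rate this reproduces the
#' qualitative fact that out-of-focus beads look different above versus
#' below the focal plane, which is what makes the sign of dZ recoverable
#' from a single image.
#'
#' All intensity parameters are fractions of the local background, which
#' itself scales linearly with exposure (`background_level` counts at
#' `exposure_ref_ms`) until values clip at `bit_depth_max`.
#'
#' @param bead_radius_px bead radius in pixels (beads are about 18-20 px in
#'   diameter at 1.5 um/px).
#' @param rim_depth darkness of the annular bead body as a fraction of
#'   background, in `[0, 1]`.
#' @param center_peak_gain peak amplitude of the bright bead center at
#'   focus, as a fraction of background.
#' @param background_level mean background intensity in counts at the
#'   reference exposure.
#' @param defocus_blur_rate disk blur radius growth, px per um of `|dz|`.
#' @param focus_sharpness_scale scale (um) over which the above-focus halo
#'   switches on.
#' @param noise_sd standard deviation of additive Gaussian read noise
#'   (counts).
#' @param bit_depth_max sensor maximum (255 for 8-bit).
#' @param rim_inner_px inner radius of the dark body annulus (px).
#' @param edge_width_px softness (sigmoid width, px) of the body edges.
#' @param center_sigma_px standard deviation (px) of the bright center peak.
#' @param halo_gain amplitude of the above-focus halo ring (fraction of
#'   background).
#' @param halo_radius_px,halo_sigma_px radial position and width of the halo
#'   ring (px).
#' @param blur_asym relative asymmetry of the blur rate above (+) versus
#'   below (-) focus.
#' @param exposure_ref_ms exposure (ms) at which `background_level` applies.
#' @param pixel_size_um physical pixel size, um per px.
#' @return an object of class `optical_model`.
#' @export
optical_model <- function(bead_radius_px = 9.5,
                          rim_depth = 0.82,
                          center_peak_gain = 1.2,
                          background_level = 85,
                          defocus_blur_rate = 0.06,
                          focus_sharpness_scale = 12,
                          noise_sd = 2,
                          bit_depth_max = 255,
                          rim_inner_px = 2.5,
                          edge_width_px = 1.3,
                          center_sigma_px = 2.5,
                          halo_gain = 0.4,
                          halo_radius_px = 13,
                          halo_sigma_px = 1.8,
                          blur_asym = 0.2,
                          exposure_ref_ms = 10,
                          pixel_size_um = 1.5) {
  stopifnot(bead_radius_px > 0, rim_depth >= 0, rim_depth <= 1,
            background_level > 0, defocus_blur_rate >= 0, noise_sd >= 0,
            bit_depth_max > 0, exposure_ref_ms > 0)
  structure(list(
    bead_radius_px = bead_radius_px, rim_depth = rim_depth,
    center_peak_gain = center_peak_gain, background_level = background_level,
    defocus_blur_rate = defocus_blur_rate,
    focus_sharpness_scale = focus_sharpness_scale, noise_sd = noise_sd,
    bit_depth_max = bit_depth_max, rim_inner_px = rim_inner_px,
    edge_width_px = edge_width_px, center_sigma_px = center_sigma_px,
    halo_gain = halo_gain, halo_radius_px = halo_radius_px,
    halo_sigma_px = halo_sigma_px, blur_asym = blur_asym,
    exposure_ref_ms = exposure_ref_ms, pixel_size_um = pixel_size_um
  ), class = "optical_model")
}

#' @export
print.optical_model <- function(x, ...) {
  cat("<optical_model>\n")
  cat(sprintf("  bead radius %.1f px, body depth %.2f, center gain %.2f\n",
              x$bead_radius_px, x$rim_depth, x$center_peak_gain))
  cat(sprintf("  background %g counts @ %g ms, blur %.3f px/um, noise sd %g\n",
              x$background_level, x$exposure_ref_ms, x$defocus_blur_rate,
              x$noise_sd))
  invisible(x)
}

#' Specification of a synthetic Z sweep
#'
#' Describes one synthetic acquisition campaign: a Z sweep of one or more
#' fields of view at one or more exposures, with a known true reference
#' effective focal plane (`true_refp`). Ground truth dZ for every acquired
#' image is `z - true_refp` (negative below the REFP).
#'
#' @param z_min,z_max,z_increment nominal Z sweep range and step (um).
#' @param exposures exposure times in ms.
#' @param n_fov number of fields of view.
#' @param beads_per_fov beads placed in each field.
#' @param true_refp the focal plane (um, nominal Z units) at which beads are
#'   most in focus.
#' @param distractor_count elongated dark debris objects per field.
#' @param seed base random seed; bead placement is fixed per field of view
#'   across the whole sweep (the sample does not move while Z changes).
#' @param experiment experiment identifier used in the manifest.
#' @param image_width,image_height field-of-view size in pixels.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(z_min = 1447.5, z_max = 1567.5, z_increment = 7.5,
                       exposures = c(6, 12, 15), n_fov = 2,
                       beads_per_fov = 8, true_refp = 1507.5,
                       distractor_count = 0, seed = 1,
                       experiment = "synthetic",
                       image_width = 768, image_height = 640) {
  if (z_max < z_min) refp_stop("invalid_argument", "z_max < z_min")
  if (z_increment <= 0) refp_stop("invalid_argument", "z_increment <= 0")
  if (true_refp < z_min || true_refp > z_max)
    warning("true_refp lies outside the sweep range; ",
            "feature extrema will sit at the sweep boundary")
  if (any(exposures <= 0)) refp_stop("invalid_argument", "exposures must be > 0")
  n_z <- round((z_max - z_min) / z_increment) + 1
  structure(list(
    z_min = z_min, z_max = z_max, z_increment = z_increment,
    z_levels = z_min + z_increment * (seq_len(n_z) - 1),
    exposures = exposures, n_fov = n_fov, beads_per_fov = beads_per_fov,
    true_refp = true_refp, distractor_count = distractor_count,
    seed = seed, experiment = experiment,
    image_width = image_width, image_height = image_height
  ), class = "sweep_spec")
}

#' @export
print.sweep_spec <- function(x, ...) {
  cat("<sweep_spec>", x$experiment, "\n")
  cat(sprintf("  Z [%g, %g] um step %g (%d levels), true REFP %g um\n",
              x$z_min, x$z_max, x$z_increment, length(x$z_levels),
              x$true_refp))
  cat(sprintf("  exposures {%s} ms, %d FOV x %d beads (+%d distractors)\n",
              paste(x$exposures, collapse = ", "), x$n_fov, x$beads_per_fov,
              x$distractor_count))
  invisible(x)
}
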