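#' Render a synthetic OCT volume
#'
#' Evaluates the forward model on a device grid: slab reflectivity times
#' exponential attenuation (bulk tissue below the ILM, excess attenuation
#' through serous fluid, device sensitivity roll-off from the top of the
#' frame), plus additive Gaussian noise, clipped at zero. Per-acquisition
#' reflectivity jitter (directional inner-retina reflectance; see
#' [device_model()]) is drawn from the seed before rendering. Output
#' intensities are snapped to single precision so that rendered volumes
#' survive disk round trips bit-exactly. Deterministic given
#' `(geometry, model, config, seed)`.
#'
#' @param geometry A `retina_geometry` from [build_geometry()].
#' @param model A [device_model()]; its `device` field must match `config`.
#' @param config A [scan_config()].
#' @param seed Integer seed for jitter and noise.
#' @param surfaces Optional pre-computed [boundary_surfaces_for()] result.
#' @param choroid [choroid_params()] delimiting Sattler/Haller reflectivity
#'   slabs.
#' @return A [scan_volume()].
#' @export
render_volume <- function(geometry, model, config, seed,
                          surfaces = NULL, choroid = choroid_params()) {
  stopifnot(inherits(geometry, "retina_geometry"), inherits(model, "device_model"))
  config <- as_scan_config(config)
  if (model$device != config$device) {
    abort(sprintf("Device model is '%s' but the scan configuration is '%s'.",
                  model$device, config$device))
  }
  if (is.null(surfaces)) surfaces <- boundary_surfaces_for(geometry, config)
  withr::local_seed(as.integer(seed))
  refl <- geometry$reflectivity
  deep_tissue <- c("rpe", "sattler", "haller", "sclera")
  refl["deep"] <- refl["deep"] * exp(rnorm(1L, 0, model$acq_jitter_sd_deep_retina))
  refl[c("superficial", "outer")] <- refl[c("superficial", "outer")] *
    exp(rnorm(2L, 0, model$acq_jitter_sd_retina))
  refl[deep_tissue] <- refl[deep_tissue] *
    exp(rnorm(4L, 0, model$acq_jitter_sd_deep_tissue))
  noise_abs <- model$noise_sd *
    mean(refl[c("superficial", "deep", "outer", deep_tissue)])
  vol <- render_volume_cpp(
    config$n_fast, config$n_slow, config$n_depth, config$axial_spacing_um,
    surfaces$ILM, surfaces$IPL, surfaces$OPL, surfaces$ISOS, surfaces$RPE,
    surfaces$BM, choroid$t_sattler_um, choroid$t_haller_um,
    as.numeric(refl[geometry_slabs]),
    model$tissue_attenuation_per_mm, model$fluid_excess_attenuation_per_mm,
    model$rolloff_per_mm, noise_abs
  )
  scan_volume(vol, config)
}

#' Synthetic macular vascular pattern
#'
#' A binary ground-truth vessel map on a fine reference grid (2 um pixels by
#' default), built from three deterministic seeded components: a perifoveal
#' capillary ring at the rim of a circular foveal avascular zone (FAZ), a set
#' of radial branching arteriolar/venular trees, and a dense mat of short
#' capillary segments. Pixels inside the FAZ are vessel-free. Because the
#' map is binary and pixel-countable, the vessel area fraction inside any
#' analysis circle is known exactly — this is the ground truth against which
#' measured vessel density is validated.
#'
#' @param seed Integer seed.
#' @param fov_mm Side length of the reference field (must cover the largest
#'   scan pattern).
#' @param faz_radius_mm FAZ radius.
#' @param ref_spacing_um Reference grid pitch.
#' @param n_trees Number of radial trees.
#' @param capillary_density Expected fraction of the field covered by the
#'   capillary mat before overlap (Boolean-model intensity).
#' @param analysis_radius_mm Circle radius used for the stored
#'   `true_vessel_fraction` (any other radius can be queried with
#'   [vessel_fraction()]).
#' @return A `vascular_pattern`: logical `map`, grid metadata, and
#'   `true_vessel_fraction`.
#' @export
vascular_pattern <- function(seed, fov_mm = 6.4, faz_radius_mm = 0.25,
                             ref_spacing_um = 2, n_trees = 10,
                             capillary_density = 0.38,
                             analysis_radius_mm = 1.4) {
  withr::local_seed(as.integer(seed))
  n <- as.integer(round(fov_mm * 1000 / ref_spacing_um))
  canvas <- matrix(FALSE, n, n)
  ctr <- (n + 1) / 2
  px_per_mm <- 1000 / ref_spacing_um

  # perifoveal capillary ring
  theta <- seq(0, 2 * pi, length.out = 145L)
  ring <- list(
    x0 = ctr + faz_radius_mm * px_per_mm * cos(theta[-length(theta)]),
    y0 = ctr + faz_radius_mm * px_per_mm * sin(theta[-length(theta)]),
    x1 = ctr + faz_radius_mm * px_per_mm * cos(theta[-1L]),
    y1 = ctr + faz_radius_mm * px_per_mm * sin(theta[-1L])
  )
  segs <- list(
    x0 = ring$x0, y0 = ring$y0, x1 = ring$x1, y1 = ring$y1,
    hw = rep(6 / ref_spacing_um / 2, length(ring$x0))
  )

  # radial branching trees
  add_seg <- function(s, x0, y0, x1, y1, hw) {
    s$x0 <- c(s$x0, x0); s$y0 <- c(s$y0, y0)
    s$x1 <- c(s$x1, x1); s$y1 <- c(s$y1, y1)
    s$hw <- c(s$hw, hw)
    s
  }
  step_px <- 0.22 * px_per_mm
  queue <- lapply(seq_len(n_trees), function(i) {
    ang <- 2 * pi * (i - 1) / n_trees + runif(1, -0.2, 0.2)
    list(x = ctr + faz_radius_mm * px_per_mm * cos(ang),
         y = ctr + faz_radius_mm * px_per_mm * sin(ang),
         ang = ang, width_um = runif(1, 28, 38))
  })
  n_emitted <- 0L
  while (length(queue) > 0L && n_emitted < 4000L) {
    br <- queue[[1L]]
    queue <- queue[-1L]
    ang <- br$ang + runif(1, -0.3, 0.3)
    x1 <- br$x + step_px * cos(ang)
    y1 <- br$y + step_px * sin(ang)
    segs <- add_seg(segs, br$x, br$y, x1, y1, br$width_um / ref_spacing_um / 2)
    n_emitted <- n_emitted + 1L
    if (x1 < 1 || x1 > n || y1 < 1 || y1 > n || br$width_um < 9) next
    if (runif(1) < 0.32) {
      split <- runif(1, 0.25, 0.45)
      queue <- c(queue, list(
        list(x = x1, y = y1, ang = ang + split, width_um = br$width_um * 0.8),
        list(x = x1, y = y1, ang = ang - split, width_um = br$width_um * 0.8)
      ))
    } else {
      queue <- c(queue, list(list(x = x1, y = y1, ang = ang,
                                  width_um = br$width_um * 0.96)))
    }
  }

  # capillary mat: short random segments at Boolean-model intensity
  seg_len_um <- 120
  seg_w_um <- 10
  n_cap <- as.integer(round(-log(1 - capillary_density) *
                              (fov_mm * 1000)^2 / (seg_len_um * seg_w_um)))
  cx <- runif(n_cap, 1, n)
  cy <- runif(n_cap, 1, n)
  ca <- runif(n_cap, 0, pi)
  cl <- seg_len_um * exp(rnorm(n_cap, 0, 0.25)) / ref_spacing_um / 2
  segs <- add_seg(segs, cx - cl * cos(ca), cy - cl * sin(ca),
                  cx + cl * cos(ca), cy + cl * sin(ca),
                  rep(seg_w_um / ref_spacing_um / 2, n_cap))

  canvas <- raster_segments_cpp(canvas, segs$x0, segs$y0, segs$x1, segs$y1, segs$hw)

  # clear the FAZ
  xs <- (seq_len(n) - ctr) / px_per_mm
  inside_faz <- outer(xs^2, xs^2, `+`) <= faz_radius_mm^2
  canvas[inside_faz] <- FALSE

  pat <- structure(
    list(map = canvas, fov_mm = fov_mm, faz_radius_mm = faz_radius_mm,
         ref_spacing_um = ref_spacing_um, seed = as.integer(seed),
         analysis_radius_mm = analysis_radius_mm),
    class = "vascular_pattern"
  )
  pat$true_vessel_fraction <- vessel_fraction(pat, analysis_radius_mm)
  pat
}

#' @export
print.vascular_pattern <- function(x, ...) {
  cat(sprintf(
    "<vascular_pattern> %.1f mm field @ %.0f um, FAZ %.2f mm, vessel fraction %.3f (r = %.2f mm)\n",
    x$fov_mm, x$ref_spacing_um, x$faz_radius_mm, x$true_vessel_fraction,
    x$analysis_radius_mm
  ))
  invisible(x)
}

#' Exact vessel area fraction of a pattern
#'
#' Fraction of vessel pixels inside a centred analysis circle, excluding the
#' FAZ disk — the ground truth corresponding to a measured vessel density.
#'
#' @param pattern A [vascular_pattern()].
#' @param radius_mm Analysis circle radius.
#' @return Fraction in `[0, 1]`.
#' @export
vessel_fraction <- function(pattern, radius_mm) {
  n <- nrow(pattern$map)
  ctr <- (n + 1) / 2
  xs <- (seq_len(n) - ctr) * pattern$ref_spacing_um / 1000
  r2 <- outer(xs^2, xs^2, `+`)
  sel <- r2 <= radius_mm^2 & r2 > pattern$faz_radius_mm^2
  mean(pattern$map[sel])
}

#' Render a device en-face angiogram from a vascular pattern
#'
#' Resamples the ground-truth vessel map onto the device grid (nearest
#' neighbour at each pixel centre), assigns vessel and background flow
#' intensities, and adds Gaussian noise clipped at zero. The FAZ remains
#' background. Output snapped to single precision.
#'
#' @param pattern A [vascular_pattern()].
#' @param config A [scan_config()]; its field must fit inside the pattern.
#' @param seed Integer seed for the noise.
#' @param vessel_intensity,background_intensity Mean flow signal in/outside
#'   vessels.
#' @param noise_sd Additive noise sd.
#' @return An [enface_angiogram()].
#' @export
render_angiogram <- function(pattern, config, seed,
                             vessel_intensity = 1, background_intensity = 0.15,
                             noise_sd = 0.08) {
  config <- as_scan_config(config)
  g <- scan_grid(config)
  half_um <- pattern$fov_mm * 1000 / 2
  if (max(abs(c(g$x_mm, g$y_mm))) * 1000 > half_um) {
    abort("Scan field extends beyond the vascular pattern's reference grid.")
  }
  to_ref <- function(pos_mm) {
    i <- as.integer(round((pos_mm * 1000 + half_um) / pattern$ref_spacing_um + 0.5))
    pmin(pmax(i, 1L), nrow(pattern$map))
  }
  vessel <- pattern$map[to_ref(g$x_mm), to_ref(g$y_mm)]
  withr::local_seed(as.integer(seed))
  img <- background_intensity + (vessel_intensity - background_intensity) * vessel
  if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
  img[img < 0] <- 0
  dim(img) <- c(config$n_fast, config$n_slow)
  enface_angiogram(float32_snap(img), config$lateral_spacing_um,
                   config$device, layer_name = "retina",
                   pattern = config$pattern)
}
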