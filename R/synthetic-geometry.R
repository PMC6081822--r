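#' Phenomenological device model
#'
#' The forward model treats each instrument as a combination of (i) a
#' depth-dependent sensitivity roll-off, stronger for the spectral-domain
#' spectrometer than for the swept laser, (ii) bulk tissue attenuation along
#' the beam, (iii) an *excess* attenuation per millimetre of serous fluid
#' traversed, larger for SD than SS by construction — this is the mechanism
#' by which a serous detachment degrades sub-lesion signal differently on the
#' two devices — and (iv) additive Gaussian detection noise. Between-scan
#' reflectivity variation models directional (beam-entry-dependent)
#' reflectance of the inner retina, which fluctuates acquisition to
#' acquisition far more than the diffusely scattering choroid.
#'
#' All rates are phenomenological conventions of the simulator, not measured
#' device constants; the defaults are chosen to reproduce the qualitative
#' ordering (SS retains deep signal better) at plausible magnitudes.
#'
#' @param device `"SD"` or `"SS"`.
#' @param rolloff_per_mm Sensitivity roll-off rate (fraction of log-signal
#'   lost per mm of depth, applied as `exp(-rate * z)`).
#' @param tissue_attenuation_per_mm Bulk attenuation per mm of tissue below
#'   the ILM.
#' @param fluid_excess_attenuation_per_mm Additional attenuation per mm of
#'   serous fluid traversed.
#' @param noise_sd Additive noise standard deviation, relative to the mean
#'   slab reflectivity.
#' @param acq_jitter_sd_deep_retina Log-scale sd of the per-acquisition
#'   reflectivity multiplier of the deep retinal slab. This slab borders
#'   Henle's fiber layer, whose reflectance depends strongly on the pupil
#'   entry position of the beam, so it fluctuates most between acquisitions.
#' @param acq_jitter_sd_retina Log-scale sd for the other retinal slabs
#'   (superficial, outer).
#' @param acq_jitter_sd_deep_tissue Log-scale sd for RPE/choroid/sclera
#'   (diffuse scatterers; nearly stable between acquisitions).
#' @return A `device_model` list.
#' @export
device_model <- function(device,
                         rolloff_per_mm,
                         tissue_attenuation_per_mm = 1.0,
                         fluid_excess_attenuation_per_mm = 0,
                         noise_sd = 0.02,
                         acq_jitter_sd_deep_retina = 0.02,
                         acq_jitter_sd_retina = 0.008,
                         acq_jitter_sd_deep_tissue = 0.003) {
  device <- match.arg(device, c("SD", "SS"))
  rates <- c(rolloff_per_mm, tissue_attenuation_per_mm,
             fluid_excess_attenuation_per_mm, noise_sd,
             acq_jitter_sd_deep_retina, acq_jitter_sd_retina,
             acq_jitter_sd_deep_tissue)
  if (any(rates < 0)) abort("Device-model rates must be non-negative.")
  structure(
    list(device = device,
         rolloff_per_mm = rolloff_per_mm,
         tissue_attenuation_per_mm = tissue_attenuation_per_mm,
         fluid_excess_attenuation_per_mm = fluid_excess_attenuation_per_mm,
         noise_sd = noise_sd,
         acq_jitter_sd_deep_retina = acq_jitter_sd_deep_retina,
         acq_jitter_sd_retina = acq_jitter_sd_retina,
         acq_jitter_sd_deep_tissue = acq_jitter_sd_deep_tissue),
    class = "device_model"
  )
}

#' Default SD/SS device models
#'
#' SD: roll-off 0.6 /mm, fluid excess attenuation 1.5 /mm. SS: roll-off
#' 0.2 /mm, fluid excess attenuation 0.5 /mm. Both share bulk tissue
#' attenuation 1.0 /mm and additive noise (sd 0.02 of mean reflectivity).
#'
#' @param noise_sd Additive noise level for both devices (0 renders
#'   noiseless volumes).
#' @return Named list with elements `SD` and `SS`.
#' @export
default_device_models <- function(noise_sd = 0.02) {
  list(
    SD = device_model("SD", rolloff_per_mm = 0.6,
                      fluid_excess_attenuation_per_mm = 1.5,
                      noise_sd = noise_sd),
    SS = device_model("SS", rolloff_per_mm = 0.2,
                      fluid_excess_attenuation_per_mm = 0.5,
                      noise_sd = noise_sd)
  )
}

geometry_slabs <- c("vitreous", "superficial", "deep", "outer", "fluid",
                    "rpe", "sattler", "haller", "sclera")

#' Baseline retina/choroid phantom parameters
#'
#' Flat-layer baseline geometry (depths in micrometres from the volume top)
#' with a 2.0 mm depth window in mind, mean linear reflectivities per slab,
#' and an optional half-ellipsoid serous detachment. The default ILM depth
#' is offset half an axial sample from the 5 um grid so that flat baseline
#' boundaries fall between voxel centres rather than exactly on them (a
#' boundary coincident with a sample centre makes whole-voxel counting
#' systematically one-sided). The IS/OS band and the
#' RPE are apposed at baseline (gap 0); a detachment displaces the IS/OS
#' surface anteriorly by the local dome height, so the IS/OS-RPE gap equals
#' the dome height and the fluid volume is exactly the dome volume
#' `(2/3) * pi * a * b * c`. The outer band is kept thick enough that the
#' tallest default dome never crosses the OPL. Reflectivities are simulator
#' conventions in arbitrary linear units (overall scale is irrelevant after
#' normalization).
#'
#' @param ilm_depth_um Depth of the ILM.
#' @param thickness_um Named numeric: slab thicknesses `superficial`,
#'   `deep`, `outer`, `rpe` (micrometres).
#' @param reflectivity Named numeric over
#'   `vitreous, superficial, deep, outer, fluid, rpe, sattler, haller,
#'   sclera`.
#' @param dome List `center_mm` (length-2), semi-axes `a_mm`, `b_mm` and
#'   height `c_mm` of the half-ellipsoid detachment (`c_mm = 0`: healthy).
#' @param subject_jitter List of log-scale sd for per-subject thickness
#'   multipliers (`thickness`), a global reflectivity scale (`scale`), and
#'   the sd (mm) of dome-centre jitter (`center_mm`); applied by
#'   [build_geometry()] when a seed is given.
#' @return A named parameter list.
#' @export
geometry_params <- function(ilm_depth_um = 252.5,
                            thickness_um = c(superficial = 120, deep = 110,
                                             outer = 450, rpe = 25),
                            reflectivity = c(vitreous = 0.01, superficial = 0.70,
                                             deep = 0.55, outer = 0.35,
                                             fluid = 0.02, rpe = 0.60,
                                             sattler = 0.14, haller = 0.11,
                                             sclera = 0.06),
                            dome = list(center_mm = c(0, 0), a_mm = 0,
                                        b_mm = 0, c_mm = 0),
                            subject_jitter = list(thickness = 0.02,
                                                  scale = 0.10,
                                                  center_mm = 0.05)) {
  stopifnot(all(c("superficial", "deep", "outer", "rpe") %in% names(thickness_um)),
            all(geometry_slabs %in% names(reflectivity)))
  list(ilm_depth_um = ilm_depth_um, thickness_um = thickness_um,
       reflectivity = reflectivity[geometry_slabs], dome = dome,
       subject_jitter = subject_jitter)
}

#' Build a subject's retinal geometry
#'
#' Instantiates the phantom for one subject: baseline surface depths, slab
#' reflectivities, dome parameters and the analytic fluid volume. With a
#' `seed`, subject-level biological variation is drawn (log-normal thickness
#' multipliers, a global reflectivity scale, dome-centre jitter); without
#' one, the parameters are used verbatim.
#'
#' @param params [geometry_params()].
#' @param seed Optional integer seed for subject-level variation.
#' @param strict Error when the dome footprint reaches outside a 3 x 3 mm
#'   field? Default `FALSE`: truncation is legitimate (large lesions overrun
#'   the small scan pattern) and is flagged downstream.
#' @return A `retina_geometry` object; field `analytic_csv_mm3` holds
#'   `(2/3) * pi * a * b * c`.
#' @export
build_geometry <- function(params = geometry_params(), seed = NULL,
                           strict = FALSE) {
  dome <- params$dome
  if (dome$a_mm < 0 || dome$b_mm < 0 || dome$c_mm < 0) {
    abort("Dome semi-axes and height must be non-negative.")
  }
  th <- params$thickness_um
  refl <- params$reflectivity
  center <- dome$center_mm
  if (!is.null(seed)) {
    withr::local_seed(as.integer(seed))
    jit <- params$subject_jitter
    th <- th * exp(rnorm(length(th), 0, jit$thickness))
    refl <- refl * exp(rnorm(1L, 0, jit$scale))
    if (dome$c_mm > 0) {
      center <- center + pmax(pmin(rnorm(2L, 0, jit$center_mm), 0.15), -0.15)
    }
  }
  if (dome$c_mm * 1000 >= th[["outer"]]) {
    abort(sprintf(
      "Dome height %.0f um reaches the OPL (outer band %.0f um); surface ordering would break.",
      dome$c_mm * 1000, th[["outer"]]
    ))
  }
  if (strict && dome$c_mm > 0 &&
      (abs(center[1]) + dome$a_mm > 1.5 || abs(center[2]) + dome$b_mm > 1.5)) {
    abort("Dome footprint extends outside the 3 x 3 mm scan field.")
  }
  depths <- c(ILM = params$ilm_depth_um)
  depths["IPL"] <- depths["ILM"] + th[["superficial"]]
  depths["OPL"] <- depths["IPL"] + th[["deep"]]
  depths["ISOS"] <- depths["OPL"] + th[["outer"]]
  depths["RPE"] <- depths["ISOS"]  # apposed at baseline
  depths["BM"] <- depths["RPE"] + th[["rpe"]]
  structure(
    list(baseline_depths_um = depths,
         reflectivity = refl,
         dome = list(center_mm = center, a_mm = dome$a_mm, b_mm = dome$b_mm,
                     c_mm = dome$c_mm),
         analytic_csv_mm3 = 2 / 3 * pi * dome$a_mm * dome$b_mm * dome$c_mm),
    class = "retina_geometry"
  )
}

#' @export
print.retina_geometry <- function(x, ...) {
  cat(sprintf(
    "<retina_geometry> ILM %.0f um; dome a=%.2f b=%.2f c=%.2f mm (CSV %.4f mm3)\n",
    x$baseline_depths_um[["ILM"]], x$dome$a_mm, x$dome$b_mm, x$dome$c_mm,
    x$analytic_csv_mm3
  ))
  invisible(x)
}

#' Dome height field of a geometry
#'
#' Height (um) of the half-ellipsoid detachment above each `(x, y)` position.
#'
#' @param geometry A `retina_geometry`.
#' @param x_mm,y_mm Numeric vectors of lateral positions (fovea at origin).
#' @return Matrix `length(x_mm) x length(y_mm)` of heights in micrometres.
#' @keywords internal
dome_height_um <- function(geometry, x_mm, y_mm) {
  d <- geometry$dome
  if (d$c_mm <= 0 || d$a_mm <= 0 || d$b_mm <= 0) {
    return(matrix(0, length(x_mm), length(y_mm)))
  }
  u2 <- outer(((x_mm - d$center_mm[1]) / d$a_mm)^2,
              ((y_mm - d$center_mm[2]) / d$b_mm)^2, `+`)
  h <- 1 - u2
  h[h < 0] <- 0
  d$c_mm * 1000 * sqrt(h)
}

#' Evaluate boundary surfaces on a device grid
#'
#' Samples the subject geometry at the pixel centres of a scan
#' configuration. The IS/OS surface is displaced anteriorly by the local
#' dome height; all other surfaces sit at their baseline depths. If the dome
#' footprint reaches the lateral edge of the field the returned object
#' carries attribute `truncated = TRUE`.
#'
#' @param geometry A `retina_geometry`.
#' @param config A [scan_config()].
#' @return A [boundary_surfaces()] object.
#' @export
boundary_surfaces_for <- function(geometry, config) {
  config <- as_scan_config(config)
  g <- scan_grid(config)
  d <- geometry$baseline_depths_um
  flat <- function(v) matrix(v, config$n_fast, config$n_slow)
  h <- dome_height_um(geometry, g$x_mm, g$y_mm)
  out <- boundary_surfaces(
    ILM = flat(d[["ILM"]]), IPL = flat(d[["IPL"]]), OPL = flat(d[["OPL"]]),
    ISOS = flat(d[["ISOS"]]) - h, RPE = flat(d[["RPE"]]), BM = flat(d[["BM"]]),
    config = config
  )
  dome <- geometry$dome
  truncated <- dome$c_mm > 0 &&
    (abs(dome$center_mm[1]) + dome$a_mm > max(g$x_mm) + config$lateral_spacing_um / 2000 ||
     abs(dome$center_mm[2]) + dome$b_mm > max(g$y_mm) + config$lateral_spacing_um / 2000)
  attr(out, "truncated") <- truncated
  out
}
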