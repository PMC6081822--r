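# Depth-index helpers. Depth sample k (1-based) is centred at
# (k - 1) * axial_spacing_um, and a voxel belongs to a slab when its centre
# lies in the half-open interval (top, bottom] -- top-inclusive only for the
# innermost retinal layer, so that voxels at shared boundaries are never
# counted twice. Comparisons carry a small tolerance so that boundaries
# placed exactly on a sample centre behave as written.

idx_first_above <- function(depth_um, ax_um, eps = 1e-6) {
  # smallest k with centre > depth
  as.integer(floor(depth_um / ax_um + eps)) + 2L
}

idx_first_at_or_above <- function(depth_um, ax_um, eps = 1e-6) {
  # smallest k with centre >= depth
  as.integer(ceiling(depth_um / ax_um - eps)) + 1L
}

idx_last_at_or_below <- function(depth_um, ax_um, eps = 1e-6) {
  # largest k with centre <= depth
  as.integer(floor(depth_um / ax_um + eps)) + 1L
}

clip_interval <- function(top, bot, n_depth) {
  clipped <- any(bot > n_depth) || any(top < 1L)
  top <- pmax(top, 1L)
  bot <- pmin(bot, n_depth)
  list(top = top, bot = bot, clipped = clipped)
}

#' Choroid sublayer thickness parameters
#'
#' Fixed slab thicknesses used to delimit Sattler's (medium-vessel) and
#' Haller's (large-vessel) choroidal layers beneath Bruch's membrane.
#' Automatic choroidal segmentation cannot be assumed to behave identically
#' on both devices, so fixed thicknesses in line with published choroidal
#' anatomy are used; the defaults (100 and 200 um) are package conventions,
#' adjustable per analysis.
#'
#' @param t_sattler_um,t_haller_um Slab thicknesses in micrometres.
#' @return A named list.
#' @export
choroid_params <- function(t_sattler_um = 100, t_haller_um = 200) {
  list(t_sattler_um = as.numeric(t_sattler_um),
       t_haller_um = as.numeric(t_haller_um))
}

#' Anatomical slab masks from boundary surfaces
#'
#' Builds the per-layer masks used for signal-strength measurement:
#' * `superficial_retina` — ILM to IPL, both boundaries inclusive;
#' * `deep_retina` — below IPL down to and including OPL;
#' * `sattler` — the first `t_sattler_um` below Bruch's membrane;
#' * `haller` — the following `t_haller_um`.
#'
#' A voxel belongs to a slab when its centre depth lies in `(top, bottom]`
#' (top-inclusive for `superficial_retina` only). Slabs reaching beyond the
#' depth window are clipped and flagged on the returned mask.
#'
#' @param surfaces A [boundary_surfaces()].
#' @param layer_name One of the four slab names above.
#' @param config A [scan_config()] (defaults to the surfaces' own).
#' @param choroid [choroid_params()] for the choroidal slabs.
#' @return A [layer_mask()].
#' @export
slab_mask <- function(surfaces, layer_name, config = surfaces$config,
                      choroid = choroid_params()) {
  stopifnot(inherits(surfaces, "boundary_surfaces"))
  config <- as_scan_config(config)
  ax <- config$axial_spacing_um
  bounds <- switch(
    layer_name,
    superficial_retina = list(top = surfaces$ILM, bot = surfaces$IPL, top_incl = TRUE),
    deep_retina = list(top = surfaces$IPL, bot = surfaces$OPL, top_incl = FALSE),
    sattler = list(top = surfaces$BM, bot = surfaces$BM + choroid$t_sattler_um,
                   top_incl = FALSE),
    haller = list(top = surfaces$BM + choroid$t_sattler_um,
                  bot = surfaces$BM + choroid$t_sattler_um + choroid$t_haller_um,
                  top_incl = FALSE),
    abort(sprintf("Unknown layer '%s'; see ?slab_mask for the slab names.", layer_name))
  )
  top_idx <- if (bounds$top_incl) {
    idx_first_at_or_above(bounds$top, ax)
  } else {
    idx_first_above(bounds$top, ax)
  }
  bot_idx <- idx_last_at_or_below(bounds$bot, ax)
  ci <- clip_interval(top_idx, bot_idx, config$n_depth)
  dim(ci$top) <- dim(bounds$top)
  dim(ci$bot) <- dim(bounds$top)
  if (ci$clipped) {
    warn(sprintf("Slab '%s' extends beyond the depth window; mask clipped.", layer_name))
  }
  layer_mask(ci$top, ci$bot, c(config$n_fast, config$n_slow, config$n_depth),
             layer_name, clipped = ci$clipped)
}

#' Serous-detachment (CSR) region mask
#'
#' Marks the fluid gap between the photoreceptor IS/OS band and the RPE
#' wherever that gap exceeds `min_gap_um`. In a healthy macula IS/OS and RPE
#' are apposed, so the threshold separates genuine detachment from normal
#' apposition (and from segmentation jitter); within a detached column the
#' mask spans the voxel centres in `(ISOS, RPE]`.
#'
#' @param surfaces A [boundary_surfaces()].
#' @param min_gap_um Minimum IS/OS-RPE separation counted as detachment.
#' @param config A [scan_config()].
#' @return A [layer_mask()] with `layer_name = "csr_region"`.
#' @export
csr_mask <- function(surfaces, min_gap_um = 10, config = surfaces$config) {
  stopifnot(inherits(surfaces, "boundary_surfaces"))
  config <- as_scan_config(config)
  ax <- config$axial_spacing_um
  gap <- surfaces$RPE - surfaces$ISOS
  top <- idx_first_above(surfaces$ISOS, ax)
  bot <- idx_last_at_or_below(surfaces$RPE, ax)
  empty <- gap <= min_gap_um
  top[empty] <- 1L
  bot[empty] <- 0L
  ci <- clip_interval(top, bot, config$n_depth)
  dim(ci$top) <- dim(gap)
  dim(ci$bot) <- dim(gap)
  layer_mask(ci$top, ci$bot, c(config$n_fast, config$n_slow, config$n_depth),
             "csr_region", clipped = ci$clipped)
}

#' Measure central serous volume (CSV) from a CSR mask
#'
#' Whole-voxel volumetry: the number of marked voxels times the voxel volume
#' (`lateral_spacing_um^2 * axial_spacing_um`), converted to cubic
#' millimetres. No partial-volume weighting is applied. The result also
#' records whether the detachment footprint touches the lateral edge of the
#' scan field, which marks measurements truncated by the field of view.
#'
#' @param mask A [layer_mask()] with `layer_name = "csr_region"` (an
#'   externally drawn mask may be supplied as a logical array via
#'   [layer_mask()] construction or dense arrays with per-column slabs).
#' @param config The [scan_config()] the mask lives on.
#' @return A one-row tibble: `volume_mm3`, `voxel_count`, `device`,
#'   `pattern`, `touches_fov_boundary`.
#' @export
measure_csv <- function(mask, config) {
  config <- as_scan_config(config)
  if (inherits(mask, "layer_mask")) {
    if (mask$layer_name != "csr_region") {
      abort(sprintf("Expected a 'csr_region' mask, got '%s'.", mask$layer_name))
    }
    count <- mask_voxel_count(mask)
    footprint <- mask$bot >= mask$top
  } else {
    count <- sum(mask)
    footprint <- apply(mask, c(1L, 2L), any)
  }
  touches <- any(footprint[1L, ]) || any(footprint[nrow(footprint), ]) ||
    any(footprint[, 1L]) || any(footprint[, ncol(footprint)])
  voxel_um3 <- config$lateral_spacing_um^2 * config$axial_spacing_um
  tibble(
    volume_mm3 = count * voxel_um3 * 1e-9,
    voxel_count = as.integer(count),
    device = config$device,
    pattern = config$pattern,
    touches_fov_boundary = touches
  )
}
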