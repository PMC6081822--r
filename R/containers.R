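#' Raw OCT intensity volume
#'
#' A 3-D array of non-negative linear-scale backscatter intensities indexed
#' `(fast, slow, depth)`, together with its acquisition configuration and
#' subject labels. Intensities are linear arbitrary units, not decibels: the
#' total-signal normalization sums backscattered energy, which is only
#' meaningful on a linear scale.
#'
#' @param intensities Numeric 3-D array, dimensions
#'   `c(n_fast, n_slow, n_depth)` of `config`, all values >= 0.
#' @param config A [scan_config()].
#' @param subject_id,eye_label Opaque labels carried through the analysis.
#'
#' @return A `scan_volume` object.
#' @export
scan_volume <- function(intensities, config, subject_id = "", eye_label = "") {
  config <- as_scan_config(config)
  d <- dim(intensities)
  expected <- c(config$n_fast, config$n_slow, config$n_depth)
  if (is.null(d) || length(d) != 3L || !all(d == expected)) {
    abort(sprintf(
      "Volume dimensions (%s) do not match configuration (%s).",
      paste(d, collapse = " x "), paste(expected, collapse = " x ")
    ))
  }
  if (anyNA(intensities) || min(intensities) < 0) {
    abort("Intensities must be non-negative and free of missing values.")
  }
  structure(
    list(intensities = intensities, config = config,
         subject_id = subject_id, eye_label = eye_label),
    class = "scan_volume"
  )
}

#' @export
print.scan_volume <- function(x, ...) {
  cat(sprintf(
    "<scan_volume> %s, %d x %d x %d voxels, subject '%s'\n",
    format(x$config), dim(x$intensities)[1], dim(x$intensities)[2],
    dim(x$intensities)[3], x$subject_id
  ))
  invisible(x)
}

new_normalized_volume <- function(values, total_raw_signal, config,
                                  subject_id = "", eye_label = "") {
  structure(
    list(values = values, total_raw_signal = total_raw_signal,
         config = config, subject_id = subject_id, eye_label = eye_label),
    class = "normalized_volume"
  )
}

#' @export
print.normalized_volume <- function(x, ...) {
  cat(sprintf(
    "<normalized_volume> %s, %d x %d x %d voxels, total raw signal %.6g\n",
    format(x$config), dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
    x$total_raw_signal
  ))
  invisible(x)
}

surface_names <- c("ILM", "IPL", "OPL", "ISOS", "RPE", "BM")

#' Layer boundary surfaces
#'
#' Six ordered depth maps (micrometres from the top of the volume, one value
#' per A-line position) delimiting the retinal slabs: inner limiting membrane
#' (ILM), inner plexiform layer bottom (IPL), outer plexiform layer bottom
#' (OPL), photoreceptor inner/outer segment junction (ISOS), retinal pigment
#' epithelium (RPE) and Bruch's membrane (BM). At every position the surfaces
#' must satisfy ILM <= IPL <= OPL <= ISOS <= RPE <= BM and lie inside the
#' depth window of `config`.
#'
#' @param ILM,IPL,OPL,ISOS,RPE,BM Numeric matrices `n_fast x n_slow`, depths
#'   in micrometres.
#' @param config A [scan_config()].
#' @return A `boundary_surfaces` object (named list of depth maps).
#' @export
boundary_surfaces <- function(ILM, IPL, OPL, ISOS, RPE, BM, config) {
  config <- as_scan_config(config)
  surfs <- list(ILM = ILM, IPL = IPL, OPL = OPL, ISOS = ISOS, RPE = RPE, BM = BM)
  dims <- c(config$n_fast, config$n_slow)
  for (nm in surface_names) {
    s <- surfs[[nm]]
    if (!is.matrix(s) || !all(dim(s) == dims)) {
      abort(sprintf("Surface %s must be a %d x %d matrix.", nm, dims[1], dims[2]))
    }
  }
  depth_max <- config$n_depth * config$axial_spacing_um
  rng <- range(unlist(lapply(surfs, range)))
  if (rng[1] < 0 || rng[2] > depth_max) {
    abort(sprintf(
      "Surface depths must lie in [0, %.0f] um; found [%.1f, %.1f].",
      depth_max, rng[1], rng[2]
    ))
  }
  for (i in seq_len(length(surface_names) - 1L)) {
    a <- surfs[[surface_names[i]]]
    b <- surfs[[surface_names[i + 1L]]]
    if (any(b - a < -1e-6)) {
      abort(sprintf(
        "Surface ordering violated: %s must not lie below %s.",
        surface_names[i], surface_names[i + 1L]
      ))
    }
  }
  structure(c(surfs, list(config = config)), class = "boundary_surfaces")
}

#' @export
print.boundary_surfaces <- function(x, ...) {
  cat(sprintf(
    "<boundary_surfaces> %s, %d x %d positions; mean depths (um): %s\n",
    format(x$config), nrow(x$ILM), ncol(x$ILM),
    paste(sprintf("%s %.0f", surface_names,
                  vapply(x[surface_names], mean, numeric(1))), collapse = ", ")
  ))
  invisible(x)
}

layer_names <- c("superficial_retina", "deep_retina", "sattler", "haller", "csr_region")

#' Layer mask (per-column depth intervals)
#'
#' A named boolean 3-D region congruent with a scan volume. Because every
#' layer used here is a slab, the mask is stored compactly as two integer
#' matrices giving, per A-line column, the first and last depth sample index
#' belonging to the layer (`top > bot` marks an empty column). Use
#' [as.array()] to expand to a dense logical array.
#'
#' @param top,bot Integer matrices `n_fast x n_slow` of 1-based first/last
#'   depth indices per column.
#' @param dim Integer vector `c(n_fast, n_slow, n_depth)` of the parent
#'   volume.
#' @param layer_name One of `r paste0('"', layer_names, '"', collapse = ", ")`.
#' @param clipped Logical flag: the slab extended beyond the depth window and
#'   was clipped.
#' @return A `layer_mask` object.
#' @export
layer_mask <- function(top, bot, dim, layer_name, clipped = FALSE) {
  layer_name <- match.arg(layer_name, layer_names)
  dim <- as.integer(dim)
  if (!all(dim(top) == dim[1:2]) || !all(dim(bot) == dim[1:2])) {
    abort("`top` and `bot` must be n_fast x n_slow matrices.")
  }
  storage.mode(top) <- "integer"
  storage.mode(bot) <- "integer"
  structure(
    list(layer_name = layer_name, top = top, bot = bot, dim = dim,
         clipped = isTRUE(clipped)),
    class = "layer_mask"
  )
}

#' @export
print.layer_mask <- function(x, ...) {
  cat(sprintf(
    "<layer_mask> '%s', %d x %d x %d, %s voxels%s\n",
    x$layer_name, x$dim[1], x$dim[2], x$dim[3],
    format(mask_voxel_count(x), big.mark = ","),
    if (x$clipped) " (clipped at depth window)" else ""
  ))
  invisible(x)
}

#' @export
as.array.layer_mask <- function(x, ...) {
  arr <- array(FALSE, dim = x$dim)
  ks <- seq_len(x$dim[3])
  for (k in ks) {
    sel <- x$top <= k & x$bot >= k
    if (any(sel)) arr[, , k][sel] <- TRUE
  }
  arr
}

#' Number of true voxels in a layer mask
#'
#' @param m A [layer_mask()] or a logical array.
#' @return Integer count.
#' @export
mask_voxel_count <- function(m) {
  if (inherits(m, "layer_mask")) {
    sum(pmax(m$bot - m$top + 1L, 0L))
  } else {
    sum(m)
  }
}

#' En-face angiogram
#'
#' A 2-D non-negative flow-intensity image on the `(fast, slow)` grid of its
#' source scan, used for vessel-density measurement.
#'
#' @param image Numeric matrix `n_fast x n_slow`, values >= 0.
#' @param lateral_spacing_um Pixel pitch in micrometres.
#' @param device `"SD"` or `"SS"`.
#' @param layer_name Label of the projected slab (e.g. `"retina"`).
#' @param pattern Optional scan-pattern label.
#' @return An `enface_angiogram` object.
#' @export
enface_angiogram <- function(image, lateral_spacing_um, device,
                             layer_name = "retina", pattern = NULL) {
  device <- match.arg(device, c("SD", "SS"))
  if (!is.matrix(image)) abort("`image` must be a matrix.")
  if (anyNA(image) || min(image) < 0) {
    abort("Angiogram values must be non-negative and free of missing values.")
  }
  structure(
    list(image = image, lateral_spacing_um = as.numeric(lateral_spacing_um),
         device = device, layer_name = layer_name, pattern = pattern),
    class = "enface_angiogram"
  )
}

#' @export
print.enface_angiogram <- function(x, ...) {
  cat(sprintf(
    "<enface_angiogram> %s '%s', %d x %d px @ %.1f um\n",
    x$device, x$layer_name, nrow(x$image), ncol(x$image), x$lateral_spacing_um
  ))
  invisible(x)
}
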