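#' Normalize an OCT volume by its total backscattered signal
#'
#' Divides every voxel by the sum of all voxel intensities in the scan, so
#' that the normalized volume integrates to one. The premise is that both
#' devices deliver (approximately) the same total light energy to the tissue
#' and absorption is negligible, so the summed backscatter approximates that
#' shared energy and rescaling by it puts the two instruments' arbitrary
#' intensity units on a common footing. The sum is taken over the entire 3-D
#' scan, not per B-scan. Accumulation uses extended-precision summation (the
#' result is independent of traversal order to well below 1e-12 relative).
#'
#' @param volume A [scan_volume()].
#' @return A `normalized_volume`: fields `values` (array summing to 1),
#'   `total_raw_signal` (the denominator), `config`, and the subject labels.
#' @export
#' @examples
#' cfg <- scan_config("SS", "3x3mm", 300, 300, 10, n_depth = 4)
#' v <- scan_volume(array(5, c(300, 300, 4)), cfg)
#' nv <- normalize_volume(v)
#' sum(nv$values)
normalize_volume <- function(volume) {
  stopifnot(inherits(volume, "scan_volume"))
  s <- sum(volume$intensities)
  if (s <= 0) {
    abort("Cannot normalize an all-zero volume: total backscattered signal is 0.")
  }
  new_normalized_volume(volume$intensities / s, s, volume$config,
                        volume$subject_id, volume$eye_label)
}

#' Per-layer signal strength
#'
#' Sums the normalized signal over a layer mask and divides by the number of
#' voxels in the layer, giving the mean normalized backscatter per voxel of
#' that layer. Because the normalized per-voxel scale depends on the total
#' voxel count of the scan grid (the unit energy is spread over more voxels
#' on a denser grid), the result also carries `value_rel`, the same mean
#' expressed in units of the volume-average voxel
#' (`value * n_total_voxels`, equivalently layer mean / volume mean of the
#' raw signal). `value_rel` is dimensionless and comparable across devices
#' with different grids; `value` is the per-voxel mean itself.
#'
#' @param x A `normalized_volume` (from [normalize_volume()]); a raw
#'   [scan_volume()] is accepted for diagnostics when `raw = TRUE`.
#' @param mask A [layer_mask()] or a logical array congruent with the volume.
#' @param raw Allow computing on unnormalized intensities.
#' @return A one-row tibble: `layer`, `device`, `pattern`, `subject_id`,
#'   `eye_label`, `layer_sum`, `voxel_count`, `value`, `value_rel`.
#' @export
layer_signal_strength <- function(x, mask, raw = FALSE) {
  if (inherits(x, "scan_volume")) {
    if (!raw) {
      abort("Pass a normalized volume (see normalize_volume()), or set raw = TRUE.")
    }
    values <- x$intensities
  } else if (inherits(x, "normalized_volume")) {
    values <- x$values
  } else {
    abort("`x` must be a scan_volume or normalized_volume.")
  }
  vdim <- dim(values)
  if (inherits(mask, "layer_mask")) {
    if (!all(mask$dim == vdim)) {
      abort(sprintf("Mask dimensions (%s) do not match volume (%s).",
                    paste(mask$dim, collapse = " x "), paste(vdim, collapse = " x ")))
    }
    res <- layer_sum_cpp(values, mask$top, mask$bot)
    layer_sum <- res$sum
    count <- res$count
    layer <- mask$layer_name
  } else {
    if (!all(dim(mask) == vdim)) {
      abort(sprintf("Mask dimensions (%s) do not match volume (%s).",
                    paste(dim(mask), collapse = " x "), paste(vdim, collapse = " x ")))
    }
    layer_sum <- sum(values[mask])
    count <- sum(mask)
    layer <- attr(mask, "layer_name") %||% NA_character_
  }
  if (count == 0L) abort("Layer mask is empty.")
  tibble(
    layer = layer,
    device = x$config$device,
    pattern = x$config$pattern,
    subject_id = x$subject_id %||% "",
    eye_label = x$eye_label %||% "",
    layer_sum = layer_sum,
    voxel_count = as.integer(count),
    value = layer_sum / count,
    value_rel = layer_sum / count * prod(vdim)
  )
}

#' Inter-device signal-strength difference
#'
#' The per-layer difference `delta = S_ss - S_sd` between swept-source and
#' spectral-domain signal strengths of the same subject, layer and scan
#' pattern. Rows of the two inputs are matched on `subject_id`, `layer` and
#' `pattern`. The default `"relative"` scale differences the
#' grid-size-independent `value_rel` (the per-voxel means of the two devices
#' sit on different normalized scales because their grids contain different
#' numbers of voxels; differencing them directly would measure the grid
#' ratio, not the optics). `scale = "per_voxel"` differences the raw
#' per-voxel means.
#'
#' @param s_ss,s_sd Tibbles from [layer_signal_strength()] with `device`
#'   `"SS"` and `"SD"` respectively (one or more rows).
#' @param scale `"relative"` (default) or `"per_voxel"`.
#' @return A tibble: `subject_id`, `layer`, `pattern`, `delta`.
#' @export
signal_strength_difference <- function(s_ss, s_sd,
                                       scale = c("relative", "per_voxel")) {
  scale <- match.arg(scale)
  if (any(s_ss$device != "SS") || any(s_sd$device != "SD")) {
    abort("`s_ss` must hold SS measurements and `s_sd` SD measurements.")
  }
  keys <- c("subject_id", "layer", "pattern")
  col <- if (scale == "relative") "value_rel" else "value"
  a <- s_ss[, c(keys, col)]
  b <- s_sd[, c(keys, col)]
  names(a)[4L] <- "value_ss"
  names(b)[4L] <- "value_sd"
  merged <- dplyr::inner_join(a, b, by = keys)
  if (nrow(merged) != nrow(a) || nrow(merged) != nrow(b)) {
    abort("SS and SD measurements do not pair up on subject, layer and pattern.")
  }
  dplyr::mutate(merged[, keys],
                delta = merged$value_ss - merged$value_sd)
}
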