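#' Maximum-intensity en-face projection of a masked volume
#'
#' Projects a (structural or flow) volume to the en-face plane: each pixel is
#' the maximum voxel value within the layer mask along its A-line; columns
#' with no masked voxel project to 0.
#'
#' @param volume A [scan_volume()].
#' @param mask A [layer_mask()] or logical array congruent with the volume.
#' @return An [enface_angiogram()] on the volume's grid.
#' @export
max_intensity_projection <- function(volume, mask) {
  stopifnot(inherits(volume, "scan_volume"))
  if (mask_voxel_count(mask) == 0L) abort("Layer mask is empty.")
  if (inherits(mask, "layer_mask")) {
    if (!all(mask$dim == dim(volume$intensities))) {
      abort("Mask dimensions do not match the volume.")
    }
    img <- mip_cpp(volume$intensities, mask$top, mask$bot)
    layer <- mask$layer_name
  } else {
    if (!all(dim(mask) == dim(volume$intensities))) {
      abort("Mask dimensions do not match the volume.")
    }
    v <- volume$intensities
    v[!mask] <- -Inf
    img <- apply(v, c(1L, 2L), max)
    img[!is.finite(img)] <- 0
    layer <- attr(mask, "layer_name") %||% "retina"
  }
  enface_angiogram(img, volume$config$lateral_spacing_um,
                   volume$config$device, layer_name = layer,
                   pattern = volume$config$pattern)
}

#' FAZ detection parameters
#'
#' @param closing_radius_um Radius of the morphological closing applied to
#'   the vessel map before looking for the central avascular component.
#' @param fallback_radius_mm Disk radius used when the connected-component
#'   approach fails (centre lands on a vessel, or the component leaks).
#' @param max_area_factor Leak guard: if the detected component exceeds this
#'   multiple of the fallback disk area, fall back to the fixed disk.
#' @return Named list.
#' @export
faz_params <- function(closing_radius_um = 30, fallback_radius_mm = 0.25,
                       max_area_factor = 16) {
  list(closing_radius_um = closing_radius_um,
       fallback_radius_mm = fallback_radius_mm,
       max_area_factor = max_area_factor)
}

px_centers_mm <- function(n, spacing_um) {
  (seq_len(n) - (n + 1) / 2) * spacing_um / 1000
}

px_circle <- function(dims, spacing_um, center_mm, radius_mm) {
  dx2 <- (px_centers_mm(dims[1], spacing_um) - center_mm[1])^2
  dy2 <- (px_centers_mm(dims[2], spacing_um) - center_mm[2])^2
  outer(dx2, dy2, `+`) <= radius_mm^2
}

#' Otsu's between-class-variance threshold
#'
#' Exhaustive histogram search for the global threshold maximizing the
#' between-class variance of the two resulting classes.
#'
#' @param x Numeric values in `[0, 1]`.
#' @param levels Number of histogram bins.
#' @return The threshold (a bin boundary in `[0, 1]`).
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L || diff(range(x)) == 0) {
    abort("Cannot threshold a constant image: no between-class variance exists.")
  }
  breaks <- seq(0, 1, length.out = levels + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  w1 <- 1 - w0
  bcv <- (mu_t * w0 - mu)^2 / (w0 * w1)
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv)
  breaks[k + 1L]
}

#' Binarize vessels within a circular region of interest
#'
#' Contrast-normalizes the intensities inside the ROI to `[0, 1]` and applies
#' a global between-class-variance (Otsu) threshold; pixels strictly above
#' the threshold are vessel. Binarization operates on each angiogram's
#' native grid (the registration transform only maps the common circle into
#' the image's frame), so no interpolation touches the intensities. The
#' method and threshold are recorded on the result for provenance. Because
#' thresholding operates on normalized contrast, the result is invariant
#' under affine intensity rescaling.
#'
#' @param angiogram An [enface_angiogram()] (or numeric matrix, taken to be
#'   in the common frame with the roi's grid spacing).
#' @param roi A `common_roi` from [register_angiograms()], or `NULL` to use
#'   the full image.
#' @param levels Histogram resolution for the threshold search.
#' @return Logical matrix (TRUE = vessel, FALSE outside the ROI) with
#'   attributes `threshold`, `method`, `spacing_um` and `center_mm` (the ROI
#'   centre in this image's frame).
#' @export
binarize_vessels <- function(angiogram, roi = NULL, levels = 256L) {
  if (inherits(angiogram, "enface_angiogram")) {
    img <- angiogram$image
    spacing <- angiogram$lateral_spacing_um
    device <- angiogram$device
  } else {
    img <- angiogram
    spacing <- roi$spacing_um %||% abort("Supply an enface_angiogram or a roi with spacing.")
    device <- "SS"
  }
  if (is.null(roi)) {
    sel <- matrix(TRUE, nrow(img), ncol(img))
    center <- c(0, 0)
  } else {
    center <- roi_center_in_frame(roi, device)
    sel <- px_circle(dim(img), spacing, center, roi$radius_mm)
  }
  vals <- img[sel]
  rng <- range(vals)
  if (diff(rng) == 0) {
    abort("Image is constant inside the ROI; no threshold exists.")
  }
  norm <- (img - rng[1]) / diff(rng)
  thr <- otsu_threshold(norm[sel], levels = levels)
  out <- norm > thr & sel
  attr(out, "threshold") <- thr
  attr(out, "method") <- "otsu_between_class_variance"
  attr(out, "spacing_um") <- spacing
  attr(out, "center_mm") <- center
  out
}

# The common ROI is expressed in the SS frame; the registration translation
# maps SD coordinates into it.
roi_center_in_frame <- function(roi, device) {
  if (identical(device, "SD")) roi$center_mm - roi$translation_mm else roi$center_mm
}

find_faz <- function(bin_map, spacing_um, center_mm = c(0, 0),
                     config = faz_params()) {
  dims <- dim(bin_map)
  r_px <- max(1L, round(config$closing_radius_um / spacing_um))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  closed <- EBImage::closing(bin_map * 1, brush) > 0.5
  ci <- round(center_mm[1] * 1000 / spacing_um + (dims[1] + 1) / 2)
  cj <- round(center_mm[2] * 1000 / spacing_um + (dims[2] + 1) / 2)
  ci <- min(max(ci, 1L), dims[1])
  cj <- min(max(cj, 1L), dims[2])
  fallback <- FALSE
  faz <- NULL
  if (!closed[ci, cj]) {
    labels <- EBImage::bwlabel(!closed)
    faz <- labels == labels[ci, cj] & !bin_map
    max_area_px <- config$max_area_factor * pi *
      (config$fallback_radius_mm * 1000 / spacing_um)^2
    if (sum(faz) > max_area_px) fallback <- TRUE
  } else {
    fallback <- TRUE
  }
  if (fallback) {
    warn("FAZ component detection failed; using the fixed-radius fallback disk.")
    faz <- px_circle(dims, spacing_um, center_mm, config$fallback_radius_mm) & !bin_map
  }
  attr(faz, "fallback") <- fallback
  attr(faz, "area_mm2") <- sum(faz) * (spacing_um / 1000)^2
  faz
}

#' Foveal avascular zone mask
#'
#' The FAZ is taken as the connected avascular component containing the ROI
#' centre after morphological closing of the vessel map (closing bridges
#' inter-capillary gaps so the perifoveal ring seals the zone). If the
#' centre lands on a vessel after closing, or the component leaks far beyond
#' a plausible foveal extent, a fixed-radius disk is used instead and the
#' result is flagged.
#'
#' @param bin_map Logical vessel map from [binarize_vessels()] (its
#'   `spacing_um`/`center_mm` attributes locate the ROI centre in the map's
#'   own frame).
#' @param roi A `common_roi`, or `NULL` with `spacing_um` given (centre =
#'   image centre).
#' @param config [faz_params()].
#' @param spacing_um Pixel pitch override, required when the map carries no
#'   spacing attribute and `roi` is `NULL`.
#' @return Logical FAZ mask with attributes `fallback` and `area_mm2`; never
#'   overlaps vessel pixels.
#' @export
exclude_faz <- function(bin_map, roi = NULL, config = faz_params(),
                        spacing_um = NULL) {
  spacing_um <- spacing_um %||% attr(bin_map, "spacing_um") %||% roi$spacing_um
  if (is.null(spacing_um)) abort("Supply `roi`, `spacing_um`, or a map from binarize_vessels().")
  center <- attr(bin_map, "center_mm") %||% (if (is.null(roi)) c(0, 0) else roi$center_mm)
  find_faz(bin_map, spacing_um, center, config)
}

shift_matrix <- function(m, dx, dy, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  src_i <- seq_len(nrow(m)) - dx
  src_j <- seq_len(ncol(m)) - dy
  ok_i <- src_i >= 1 & src_i <= nrow(m)
  ok_j <- src_j >= 1 & src_j <= ncol(m)
  out[ok_i, ok_j] <- m[src_i[ok_i], src_j[ok_j]]
  out
}

#' Register paired SD/SS angiograms and find the common circular ROI
#'
#' Resamples the SD angiogram onto the SS grid in physical (mm) coordinates
#' (bilinear interpolation — the scale factor is fixed by the known pixel
#' pitches), estimates the residual translation by maximizing the normalized
#' cross-correlation over an integer search window, then centres the largest
#' circle fitting inside both transformed fields on the fovea (the FAZ
#' centroid of the SS image, whose 3 x 3 mm grid is the denser of the two).
#'
#' @param a_sd,a_ss [enface_angiogram()]s of the same eye and scan pattern
#'   from the SD and SS device respectively.
#' @param search_px Translation search half-window (common-grid pixels).
#' @param corr_floor Registration fails (error) if the correlation peak is
#'   below this.
#' @param faz_config [faz_params()] for fovea localization.
#' @return A `common_roi`: `center_mm`, `radius_mm`, `translation_mm`,
#'   `translation_px`, `ncc_peak`, `spacing_um`, and the aligned images
#'   `sd_aligned`, `ss_aligned` on the common grid.
#' @export
register_angiograms <- function(a_sd, a_ss, search_px = 6L, corr_floor = 0.2,
                                faz_config = faz_params()) {
  stopifnot(inherits(a_sd, "enface_angiogram"), inherits(a_ss, "enface_angiogram"))
  if (a_sd$device != "SD" || a_ss$device != "SS") {
    abort("`a_sd` must be the SD image and `a_ss` the SS image.")
  }
  if (!is.null(a_sd$pattern) && !is.null(a_ss$pattern) &&
      a_sd$pattern != a_ss$pattern) {
    abort("The two angiograms come from different scan patterns.")
  }
  sp_ss <- a_ss$lateral_spacing_um
  x_sd <- px_centers_mm(nrow(a_sd$image), a_sd$lateral_spacing_um)
  y_sd <- px_centers_mm(ncol(a_sd$image), a_sd$lateral_spacing_um)
  x_ss <- px_centers_mm(nrow(a_ss$image), sp_ss)
  y_ss <- px_centers_mm(ncol(a_ss$image), sp_ss)
  xp <- pmin(pmax(rep(x_ss, times = length(y_ss)), min(x_sd)), max(x_sd))
  yp <- pmin(pmax(rep(y_ss, each = length(x_ss)), min(y_sd)), max(y_sd))
  sd_res <- matrix(
    pracma::interp2(x = y_sd, y = x_sd, Z = a_sd$image, xp = yp, yp = xp,
                    method = "linear"),
    nrow = length(x_ss)
  )
  sd_res[is.na(sd_res) | sd_res < 0] <- 0
  ss_img <- a_ss$image
  s <- as.integer(search_px)
  n1 <- nrow(ss_img); n2 <- ncol(ss_img)
  core_i <- (1L + s):(n1 - s)
  core_j <- (1L + s):(n2 - s)
  ref <- as.vector(ss_img[core_i, core_j])
  best <- c(cor = -Inf, dx = 0, dy = 0)
  for (dy in -s:s) {
    for (dx in -s:s) {
      cand <- as.vector(sd_res[core_i - dx, core_j - dy])
      cc <- suppressWarnings(stats::cor(cand, ref))
      if (is.finite(cc) && cc > best["cor"]) best <- c(cor = cc, dx = dx, dy = dy)
    }
  }
  if (!is.finite(best["cor"]) || best["cor"] < corr_floor) {
    abort(sprintf(
      "Registration failure: correlation peak %.3f below floor %.2f.",
      best["cor"], corr_floor
    ))
  }
  dx <- best[["dx"]]; dy <- best[["dy"]]
  sd_aligned <- shift_matrix(sd_res, dx, dy)

  # fovea: FAZ centroid of the SS image
  ss_bin <- binarize_vessels(a_ss, roi = NULL)
  faz <- find_faz(ss_bin, sp_ss, c(0, 0), faz_config)
  idx <- which(faz, arr.ind = TRUE)
  center_mm <- c(mean(x_ss[idx[, 1L]]), mean(y_ss[idx[, 2L]]))

  # largest circle inside both fields (SD field shifted by the translation)
  half_ss <- c(n1, n2) * sp_ss / 2000
  half_sd <- c(nrow(a_sd$image), ncol(a_sd$image)) * a_sd$lateral_spacing_um / 2000
  t_mm <- c(dx, dy) * sp_ss / 1000
  slack <- c(
    half_ss[1] - abs(center_mm[1]), half_ss[2] - abs(center_mm[2]),
    half_sd[1] - abs(center_mm[1] - t_mm[1]),
    half_sd[2] - abs(center_mm[2] - t_mm[2])
  )
  radius_mm <- min(slack)
  if (radius_mm <= 0) abort("No common circular region: fields do not overlap at the fovea.")

  structure(
    list(center_mm = center_mm, radius_mm = radius_mm,
         translation_mm = t_mm, translation_px = c(dx, dy),
         ncc_peak = unname(best[["cor"]]), spacing_um = sp_ss,
         sd_aligned = enface_angiogram(sd_aligned, sp_ss, "SD",
                                       a_sd$layer_name, a_sd$pattern),
         ss_aligned = a_ss),
    class = "common_roi"
  )
}

#' @export
print.common_roi <- function(x, ...) {
  cat(sprintf(
    "<common_roi> centre (%.3f, %.3f) mm, radius %.3f mm, shift (%.0f, %.0f) px, NCC %.3f\n",
    x$center_mm[1], x$center_mm[2], x$radius_mm,
    x$translation_px[1], x$translation_px[2], x$ncc_peak
  ))
  invisible(x)
}

#' Vessel density within the common ROI excluding the FAZ
#'
#' `density = 100 * (vessel pixels in ROI \ FAZ) / (pixels in ROI \ FAZ)`.
#' FAZ pixels contribute to neither numerator nor denominator.
#'
#' @param bin_map Logical vessel map on the common grid.
#' @param roi A `common_roi`.
#' @param faz_mask Logical FAZ mask from [exclude_faz()].
#' @param device,pattern Optional labels copied into the result.
#' @return One-row tibble: `density_percent`, `faz_area_mm2`,
#'   `roi_radius_mm`, `device`, `pattern`.
#' @export
vessel_density <- function(bin_map, roi, faz_mask, device = NA_character_,
                           pattern = NA_character_) {
  if (!all(dim(bin_map) == dim(faz_mask))) {
    abort("Vessel map and FAZ mask have different dimensions.")
  }
  spacing <- attr(bin_map, "spacing_um") %||% roi$spacing_um
  center <- attr(bin_map, "center_mm") %||% roi$center_mm
  sel <- px_circle(dim(bin_map), spacing, center, roi$radius_mm)
  denom <- sel & !faz_mask
  if (!any(denom)) abort("ROI is empty after FAZ exclusion.")
  tibble(
    density_percent = 100 * sum(bin_map & denom) / sum(denom),
    faz_area_mm2 = attr(faz_mask, "area_mm2") %||%
      (sum(faz_mask) * (spacing / 1000)^2),
    roi_radius_mm = roi$radius_mm,
    device = device,
    pattern = pattern
  )
}
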