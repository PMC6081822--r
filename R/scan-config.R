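nominal_scan_width_um <- c("3x3mm" = 3000, "6x6mm" = 6000)

#' Scan-pattern configuration
#'
#' Describes one acquisition protocol of one device: the en-face sampling grid
#' (A-lines per B-scan and B-scan locations), the lateral pixel pitch, the
#' axial (depth) sampling, and the number of repeated B-scans per location.
#' The lateral grids of the four built-in protocols are instrument facts; the
#' depth window is not reported by either instrument, so `axial_spacing_um`
#' defaults to 5 (matching the ~5 um axial resolution of both devices) and
#' `n_depth` to 400, i.e. a 2.0 mm depth window.
#'
#' @param device `"SD"` (spectral domain) or `"SS"` (swept source).
#' @param pattern `"3x3mm"` or `"6x6mm"` scan pattern.
#' @param n_fast,n_slow Number of A-lines per B-scan / of B-scan locations.
#' @param lateral_spacing_um Lateral pixel pitch in micrometres. The pitch
#'   times the grid size must match the nominal scan width (3000 or 6000 um)
#'   within one pitch unit.
#' @param axial_spacing_um Depth sampling interval in micrometres.
#' @param n_depth Number of depth samples per A-line.
#' @param repeats B-scan repetitions per slow-axis location.
#'
#' @return A `scan_config` object (a validated named list).
#' @seealso [builtin_scan_configs()]
#' @export
#' @examples
#' scan_config("SS", "3x3mm", 300, 300, 10)
scan_config <- function(device, pattern, n_fast, n_slow, lateral_spacing_um,
                        axial_spacing_um = 5, n_depth = 400L, repeats = 2L) {
  device <- match.arg(device, c("SD", "SS"))
  pattern <- match.arg(pattern, c("3x3mm", "6x6mm"))
  cfg <- structure(
    list(
      device = device, pattern = pattern,
      n_fast = as.integer(n_fast), n_slow = as.integer(n_slow),
      lateral_spacing_um = as.numeric(lateral_spacing_um),
      axial_spacing_um = as.numeric(axial_spacing_um),
      n_depth = as.integer(n_depth), repeats = as.integer(repeats)
    ),
    class = "scan_config"
  )
  validate_scan_config(cfg)
}

validate_scan_config <- function(cfg) {
  counts <- c(cfg$n_fast, cfg$n_slow, cfg$n_depth, cfg$repeats)
  if (any(!is.finite(counts)) || any(counts < 1L)) {
    abort("n_fast, n_slow, n_depth and repeats must be positive integers.")
  }
  if (cfg$lateral_spacing_um <= 0 || cfg$axial_spacing_um <= 0) {
    abort("Pixel spacings must be positive.")
  }
  width <- nominal_scan_width_um[[cfg$pattern]]
  for (n in c(cfg$n_fast, cfg$n_slow)) {
    if (abs(n * cfg$lateral_spacing_um - width) > cfg$lateral_spacing_um) {
      abort(sprintf(
        "Grid of %d px at %.1f um spans %.1f um; expected %d um within one pixel.",
        n, cfg$lateral_spacing_um, n * cfg$lateral_spacing_um, width
      ))
    }
  }
  cfg
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf(
    "<scan_config> %s %s: %d x %d A-lines @ %.1f um, %d depth samples @ %.1f um, %d repeats\n",
    x$device, x$pattern, x$n_fast, x$n_slow, x$lateral_spacing_um,
    x$n_depth, x$axial_spacing_um, x$repeats
  ))
  invisible(x)
}

#' @export
format.scan_config <- function(x, ...) {
  sprintf("%s %s", x$device, x$pattern)
}

#' Built-in device scan protocols
#'
#' The four acquisition protocols compared throughout the package: the SD
#' instrument images 3 x 3 mm with 245 x 245 A-lines (12.2 um pitch, 4
#' repeats) and 6 x 6 mm with 350 x 350 (17.1 um, 2 repeats); the SS
#' instrument images 3 x 3 mm with 300 x 300 (10 um, 4 repeats) and 6 x 6 mm
#' with 500 x 500 (12 um, 2 repeats).
#'
#' @param axial_spacing_um,n_depth Depth sampling shared by all four
#'   protocols (see [scan_config()] for the defaults' rationale).
#'
#' @return A tibble with one row per protocol and the columns of
#'   [scan_config()]; use [get_scan_config()] to fetch one as an object.
#' @export
#' @examples
#' builtin_scan_configs()
builtin_scan_configs <- function(axial_spacing_um = 5, n_depth = 400L) {
  tibble(
    device = c("SD", "SD", "SS", "SS"),
    pattern = c("3x3mm", "6x6mm", "3x3mm", "6x6mm"),
    n_fast = c(245L, 350L, 300L, 500L),
    n_slow = c(245L, 350L, 300L, 500L),
    lateral_spacing_um = c(12.2, 17.1, 10, 12),
    axial_spacing_um = axial_spacing_um,
    n_depth = as.integer(n_depth),
    repeats = c(4L, 2L, 4L, 2L)
  )
}

#' Fetch one built-in scan configuration
#'
#' @inheritParams scan_config
#' @param ... Overrides passed on to [scan_config()] (e.g. `n_depth`).
#' @return A `scan_config` object.
#' @export
#' @examples
#' get_scan_config("SD", "3x3mm")
get_scan_config <- function(device, pattern, ...) {
  tab <- builtin_scan_configs()
  row <- tab[tab$device == device & tab$pattern == pattern, ]
  if (nrow(row) != 1L) {
    abort(sprintf("No built-in configuration for device '%s', pattern '%s'.", device, pattern))
  }
  args <- modifyList(as.list(row), list(...))
  do.call(scan_config, args)
}

as_scan_config <- function(x) {
  if (inherits(x, "scan_config")) return(x)
  if (is.list(x)) return(do.call(scan_config, x[names(x) %in% names(formals(scan_config))]))
  abort("Cannot interpret `config`; supply a scan_config object.")
}

#' Physical pixel-centre coordinates of a scan grid
#'
#' Lateral pixel centres in millimetres, centred on the scan field (the fovea
#' is at the origin), and depth-sample centres in micrometres measured from
#' the top of the volume. Depth sample `k` (1-based) is centred at
#' `(k - 1) * axial_spacing_um`.
#'
#' @param config A [scan_config()].
#' @return A list with numeric vectors `x_mm`, `y_mm`, `z_um`.
#' @keywords internal
scan_grid <- function(config) {
  sp <- config$lateral_spacing_um / 1000
  list(
    x_mm = (seq_len(config$n_fast) - (config$n_fast + 1) / 2) * sp,
    y_mm = (seq_len(config$n_slow) - (config$n_slow + 1) / 2) * sp,
    z_um = (seq_len(config$n_depth) - 1) * config$axial_spacing_um
  )
}
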