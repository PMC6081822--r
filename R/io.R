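sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".yml")

config_to_meta <- function(config) {
  config[c("device", "pattern", "n_fast", "n_slow", "lateral_spacing_um",
           "axial_spacing_um", "n_depth", "repeats")]
}

#' Write / read an OCT volume as multi-page TIFF with a metadata sidecar
#'
#' One float32 TIFF page per slow-axis B-scan (rows = depth samples, columns
#' = A-lines) plus a plain-text YAML sidecar holding the scan configuration
#' and subject labels. The round trip is bit-exact for single-precision data
#' (all renderer output; see [float32_snap()]).
#'
#' @param volume A [scan_volume()].
#' @param path TIFF file path; the sidecar is written next to it with a
#'   `.yml` extension.
#' @return `write_volume()` returns `path` invisibly; `read_volume()` returns
#'   a [scan_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "scan_volume"))
  pages <- lapply(seq_len(volume$config$n_slow), function(j) {
    t(volume$intensities[, j, ])
  })
  write_tiff_float32(pages, path)
  meta <- c(config_to_meta(volume$config),
            list(subject_id = volume$subject_id, eye_label = volume$eye_label,
                 content = "oct_volume", sample_format = "float32"))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' @rdname write_volume
#' @param metadata Optional metadata record (a named list with the fields of
#'   [scan_config()] plus `subject_id`/`eye_label`); when `NULL` the YAML
#'   sidecar written by [write_volume()] is read.
#' @export
read_volume <- function(path, metadata = NULL) {
  pages <- read_tiff_pages(path)
  if (is.null(metadata)) {
    sp <- sidecar_path(path)
    if (!file.exists(sp)) abort(sprintf("Metadata sidecar not found: '%s'.", sp))
    metadata <- yaml::read_yaml(sp)
  }
  cfg <- do.call(scan_config, metadata[names(metadata) %in% names(formals(scan_config))])
  stack_dim <- c(ncol(pages[[1L]]), length(pages), nrow(pages[[1L]]))
  expected <- c(cfg$n_fast, cfg$n_slow, cfg$n_depth)
  if (!all(stack_dim == expected)) {
    abort(sprintf(
      "Image stack is %s but metadata declares %s (fast x slow x depth).",
      paste(stack_dim, collapse = " x "), paste(expected, collapse = " x ")
    ))
  }
  vol <- array(0, dim = expected)
  for (j in seq_along(pages)) vol[, j, ] <- t(pages[[j]])
  scan_volume(vol, cfg,
              subject_id = metadata$subject_id %||% "",
              eye_label = metadata$eye_label %||% "")
}

#' Write / read an en-face angiogram as a single-page TIFF
#'
#' @param angiogram An [enface_angiogram()].
#' @param path TIFF file path (YAML sidecar written alongside).
#' @return `write_angiogram()` returns `path` invisibly; `read_angiogram()`
#'   an [enface_angiogram()].
#' @export
write_angiogram <- function(angiogram, path) {
  stopifnot(inherits(angiogram, "enface_angiogram"))
  write_tiff_float32(t(angiogram$image), path)
  yaml::write_yaml(
    list(lateral_spacing_um = angiogram$lateral_spacing_um,
         device = angiogram$device, layer_name = angiogram$layer_name,
         pattern = angiogram$pattern, content = "enface_angiogram"),
    sidecar_path(path)
  )
  invisible(path)
}

#' @rdname write_angiogram
#' @param metadata Optional named list overriding the YAML sidecar.
#' @export
read_angiogram <- function(path, metadata = NULL) {
  pages <- read_tiff_pages(path)
  if (is.null(metadata)) metadata <- yaml::read_yaml(sidecar_path(path))
  enface_angiogram(t(pages[[1L]]),
                   lateral_spacing_um = metadata$lateral_spacing_um,
                   device = metadata$device,
                   layer_name = metadata$layer_name %||% "retina",
                   pattern = metadata$pattern)
}

#' Write / read boundary surfaces as tab-separated depth grids
#'
#' One TSV grid (micrometres, full double precision) per surface plus a YAML
#' record of the scan configuration.
#'
#' @param surfaces A [boundary_surfaces()] object.
#' @param prefix Path prefix; files are written as `<prefix>_<SURFACE>.tsv`
#'   and `<prefix>_config.yml`.
#' @return `write_boundary_surfaces()` returns `prefix` invisibly;
#'   `read_boundary_surfaces()` a [boundary_surfaces()].
#' @export
write_boundary_surfaces <- function(surfaces, prefix) {
  stopifnot(inherits(surfaces, "boundary_surfaces"))
  for (nm in surface_names) {
    m <- surfaces[[nm]]
    lines <- apply(m, 1L, function(row) paste(sprintf("%.17g", row), collapse = "\t"))
    writeLines(lines, sprintf("%s_%s.tsv", prefix, nm))
  }
  yaml::write_yaml(config_to_meta(surfaces$config), sprintf("%s_config.yml", prefix))
  invisible(prefix)
}

#' @rdname write_boundary_surfaces
#' @param config Optional [scan_config()]; when `NULL` the YAML record
#'   written by [write_boundary_surfaces()] is read.
#' @export
read_boundary_surfaces <- function(prefix, config = NULL) {
  if (is.null(config)) {
    config <- do.call(scan_config, yaml::read_yaml(sprintf("%s_config.yml", prefix)))
  }
  config <- as_scan_config(config)
  surfs <- lapply(surface_names, function(nm) {
    f <- sprintf("%s_%s.tsv", prefix, nm)
    if (!file.exists(f)) abort(sprintf("Surface file not found: '%s'.", f))
    m <- as.matrix(utils::read.table(f, sep = "\t", header = FALSE,
                                     colClasses = "numeric"))
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
    m
  })
  names(surfs) <- surface_names
  do.call(boundary_surfaces, c(surfs, list(config = config)))
}
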