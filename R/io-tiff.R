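# Minimal uncompressed float32 TIFF writer.
#
# Volumes and angiograms are stored as IEEE 754 single-precision samples so
# that linear intensities (which exceed 1 and must not be quantized) survive
# a round trip bit-exactly. tiff::readTIFF() reads this sample format
# exactly, but tiff::writeTIFF() only emits integer samples, so the writer
# side is implemented here: classic little-endian TIFF, one strip per page,
# no compression.

tiff_types <- c(SHORT = 3L, LONG = 4L)

tiff_entry <- function(tag, type, count, value) {
  c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(tiff_types[[type]], raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    writeBin(as.integer(value), raw(), size = 4, endian = "little"))
}

#' Write matrices as a float32 multi-page TIFF
#'
#' @param pages A matrix or list of numeric matrices (rows are image rows).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @keywords internal
write_tiff_float32 <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  n <- length(pages)
  sizes <- vapply(pages, function(p) 4L * length(p), integer(1))
  data_offsets <- 8L + cumsum(c(0L, head(sizes, -1L)))
  ifd_size <- 2L + 10L * 12L + 4L
  ifd_offsets <- 8L + sum(sizes) + (seq_len(n) - 1L) * ifd_size

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offsets[1L], con, size = 4, endian = "little")
  for (p in pages) {
    writeBin(as.vector(t(p)), con, size = 4, endian = "little")
  }
  for (i in seq_len(n)) {
    p <- pages[[i]]
    entries <- c(
      tiff_entry(256L, "LONG", 1L, ncol(p)),
      tiff_entry(257L, "LONG", 1L, nrow(p)),
      tiff_entry(258L, "SHORT", 1L, 32L),
      tiff_entry(259L, "SHORT", 1L, 1L),
      tiff_entry(262L, "SHORT", 1L, 1L),
      tiff_entry(273L, "LONG", 1L, data_offsets[i]),
      tiff_entry(277L, "SHORT", 1L, 1L),
      tiff_entry(278L, "LONG", 1L, nrow(p)),
      tiff_entry(279L, "LONG", 1L, sizes[i]),
      tiff_entry(339L, "SHORT", 1L, 3L)
    )
    writeBin(10L, con, size = 2, endian = "little")
    writeBin(entries, con)
    nxt <- if (i < n) ifd_offsets[i + 1L] else 0L
    writeBin(nxt, con, size = 4, endian = "little")
  }
  invisible(path)
}

read_tiff_pages <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  pages
}

#' Round doubles to single precision
#'
#' Snaps values to the nearest IEEE 754 float32, the storage precision of all
#' image files written by the package. The synthetic renderer applies this to
#' its output so that rendered data survive disk round trips bit-exactly.
#'
#' @param x Numeric vector/array.
#' @return `x` with every element representable in single precision.
#' @export
float32_snap <- function(x) {
  out <- float32_snap_cpp(as.numeric(x))
  attributes(out) <- attributes(x)
  out
}
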