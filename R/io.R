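#' Write a phase image as 32-bit float TIFF
#'
#' Writes a single-channel, single-strip, uncompressed little-endian TIFF
#' with IEEE float samples (radians stored as-is, no scaling).  This float
#' layout is produced directly because mainstream R TIFF writers only emit
#' integer samples normalised to [0, 1]; the files read back with
#' [read_phase()] / `tiff::readTIFF()` and with any standard TIFF reader.
#'
#' @param phase A `phase_image` or numeric matrix (radians).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phase <- function(phase, path) {
  v <- phase_values(phase)
  h <- nrow(v); w <- ncol(v)
  data_len <- 4L * h * w
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L + data_len, con, size = 4, endian = "little")  # IFD offset
  writeBin(as.numeric(t(v)), con, size = 4, endian = "little")  # row-major
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT: value in the low 2 bytes, zero pad
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(10L, con, size = 2, endian = "little")  # entry count
  entry(256, 4, 1, w)         # ImageWidth
  entry(257, 4, 1, h)         # ImageLength
  entry(258, 3, 1, 32)        # BitsPerSample
  entry(259, 3, 1, 1)         # Compression: none
  entry(262, 3, 1, 1)         # Photometric: BlackIsZero
  entry(273, 4, 1, 8)         # StripOffsets: data starts after header
  entry(277, 3, 1, 1)         # SamplesPerPixel
  entry(278, 4, 1, h)         # RowsPerStrip
  entry(279, 4, 1, data_len)  # StripByteCounts
  entry(339, 3, 1, 3)         # SampleFormat: IEEE float
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  invisible(path)
}

#' Read a phase image from a float TIFF
#'
#' @param path TIFF file (32-bit float samples, as written by
#'   [write_phase()] or any standard tool).
#' @param wrapped Logical flag to attach to the result.
#' @return A `phase_image`.
#' @export
read_phase <- function(path, wrapped = FALSE) {
  v <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(v)) == 3) v <- v[, , 1]
  # float32 rounding can push stored principal values a hair past pi
  if (wrapped) v <- wrap_values(v)
  phase_image(v, wrapped = wrapped)
}

#' Write / read a binary mask as 8-bit PNG
#'
#' Masks are stored as 8-bit grayscale PNG with values {0, 255}.
#'
#' @param mask 0/1 integer matrix.
#' @param path File path.
#' @return `write_mask`: `path`, invisibly; `read_mask`: a 0/1 integer
#'   matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3) v <- v[, , 1]
  m <- matrix(as.integer(v > 0.5), nrow(v), ncol(v))
  m
}

#' Read an aberration spec from YAML
#'
#' The YAML maps `"k,l"` keys to coefficients, e.g.
#' \preformatted{coefficients:
#'   "2,0": 1.0e-5
#'   "3,1": 1.0e-11}
#'
#' @param x Path to a YAML file, or an already-parsed list with a
#'   `coefficients` entry (or the coefficients map itself).
#' @return An [aberration_spec()].
#' @export
read_aberration_yaml <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  coefs <- if (!is.null(cfg$coefficients)) cfg$coefficients else cfg
  if (length(coefs) == 0) stop("no coefficients found")
  kl <- lapply(strsplit(names(coefs), ","), as.numeric)
  aberration_spec(
    k = vapply(kl, `[`, 1, i = 1),
    l = vapply(kl, `[`, 2, i = 2),
    value = as.numeric(unlist(coefs))
  )
}

#' Write an aberration spec to YAML
#'
#' @param spec An [aberration_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aberration_yaml <- function(spec, path) {
  coefs <- as.list(spec$value)
  names(coefs) <- paste(spec$k, spec$l, sep = ",")
  yaml::write_yaml(list(coefficients = coefs), path)
  invisible(path)
}

#' Serialize a compensation report to JSON
#'
#' Writes the per-step summaries (derivative order, axis, PC1 variance
#' fraction, background STD), the STD trace and the stop reason; the
#' image-sized surfaces are left to TIFF output.
#'
#' @param report A `dpca_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "dpca_report"))
  steps <- lapply(report$steps, function(s) {
    list(j = s$j, axis = s$axis, background_std = s$background_std,
         pc1_fraction = s$pc1_fraction)
  })
  jsonlite::write_json(
    list(steps = steps, std_trace = report$std_trace,
         stop_reason = report$stop_reason),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
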