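#' Minimal single-frame grayscale DICOM reader
#'
#' Parses uncompressed little-endian DICOM (explicit or implicit VR) far
#' enough to recover the pixel grid and the metadata this pipeline needs:
#' rows/columns, bits allocated/stored, pixel spacing, samples per pixel,
#' number of frames, and rescale slope/intercept. Anything outside that
#' profile (compressed transfer syntaxes, colour, multi-frame) is rejected.
#'
#' @param path path to a DICOM file.
#' @return list with `pixels` (integer matrix), `bit_depth`,
#'   `pixel_spacing` (mm, or `NA` if absent), `rows`, `cols`.
#' @seealso [write_dicom()] for the matching writer used to build
#'   synthetic fixtures.
#' @export
read_dicom <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140) stop("unreadable DICOM file: ", path)
  pos <- 1L
  if (rawToChar(raw[129:132]) == "DICM") pos <- 133L
  tags <- list()
  n <- length(raw)
  le16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  le32 <- function(i) {
    as.numeric(raw[i]) + 256 * as.numeric(raw[i + 1L]) +
      65536 * as.numeric(raw[i + 2L]) + 16777216 * as.numeric(raw[i + 3L])
  }
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n) {
    group <- le16(pos)
    elem <- le16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    explicit <- grepl("^[A-Z]{2}$", vr)
    if (group == 2L) explicit <- TRUE  # file meta is always explicit
    if (explicit) {
      if (vr %in% long_vrs) {
        len <- le32(pos + 8L)
        data_at <- pos + 12L
      } else {
        len <- le16(pos + 6L)
        data_at <- pos + 8L
      }
    } else {
      vr <- NA_character_
      len <- le32(pos + 4L)
      data_at <- pos + 8L
    }
    if (len == 4294967295) stop("undefined-length elements are unsupported")
    key <- sprintf("%04x%04x", group, elem)
    if (data_at + len - 1L > n) stop("truncated DICOM element ", key)
    tags[[key]] <- list(vr = vr, bytes = raw[data_at + seq_len(len) - 1L])
    pos <- data_at + len
    if (key == "7fe00010") break
  }
  get_str <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    trimws(rawToChar(t$bytes))
  }
  get_us <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    as.integer(t$bytes[1]) + 256L * as.integer(t$bytes[2])
  }
  ts <- get_str("00020010")
  if (!is.null(ts) && !ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")) {
    stop("unsupported transfer syntax: ", ts)
  }
  samples <- get_us("00280002") %||% 1L
  if (samples != 1L) stop("unsupported format: color (samples per pixel > 1)")
  frames <- suppressWarnings(as.integer(get_str("00280008") %||% "1"))
  if (!is.na(frames) && frames > 1L) stop("unsupported format: multi-frame image")
  rows <- get_us("00280010")
  cols <- get_us("00280011")
  bits_alloc <- get_us("00280100") %||% 16L
  bits_stored <- get_us("00280101") %||% bits_alloc
  if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns metadata")
  spacing <- NA_real_
  sp <- get_str("00280030")
  if (!is.null(sp)) {
    parts <- as.numeric(strsplit(sp, "\\\\")[[1]])
    if (length(parts) >= 1 && all(is.finite(parts))) {
      if (length(parts) == 2 && abs(parts[1] - parts[2]) > 1e-9) {
        stop("anisotropic pixel spacing is unsupported")
      }
      spacing <- parts[1]
    }
  }
  pd <- tags[["7fe00010"]]
  if (is.null(pd)) stop("missing PixelData")
  bytes_per <- bits_alloc %/% 8L
  npix <- rows * cols
  if (length(pd$bytes) < npix * bytes_per) stop("truncated PixelData")
  vals <- if (bytes_per == 2L) {
    readBin(pd$bytes, "integer", n = npix, size = 2L, signed = FALSE,
            endian = "little")
  } else {
    as.integer(pd$bytes[seq_len(npix)])
  }
  slope <- suppressWarnings(as.numeric(get_str("00281053") %||% "1"))
  inter <- suppressWarnings(as.numeric(get_str("00281052") %||% "0"))
  if (is.finite(slope) && is.finite(inter) && (slope != 1 || inter != 0)) {
    vals <- as.integer(round_half_away(vals * slope + inter))
  }
  # DICOM PixelData is row-major
  pixels <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  list(pixels = pixels, bit_depth = bits_stored, pixel_spacing = spacing,
       rows = rows, cols = cols)
}

#' Write a minimal single-frame grayscale DICOM file
#'
#' Explicit-VR little-endian writer covering exactly the profile
#' [read_dicom()] parses. Used to build synthetic scan files; it makes no
#' attempt at a clinically complete header.
#'
#' @param pixels integer matrix of non-negative intensities.
#' @param path output path.
#' @param bit_depth stored bit depth (8 or 12/16 container chosen from it).
#' @param pixel_spacing isotropic pixel spacing in mm, or `NA` to omit.
#' @param patient_id string written to PatientID.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(pixels, path, bit_depth = 12L, pixel_spacing = NA,
                        patient_id = "anon") {
  stopifnot(is.matrix(pixels))
  L <- 2^bit_depth - 1
  v <- as.vector(pixels)
  if (any(v < 0) || any(v > L)) stop("pixel values exceed the stated bit depth")
  bits_alloc <- if (bit_depth > 8L) 16L else 8L
  u16 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
  u32 <- function(x) {
    x <- as.numeric(x)
    as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
             (x %/% 16777216) %% 256))
  }
  pad_even <- function(s) {
    b <- charToRaw(s)
    if (length(b) %% 2L == 1L) b <- c(b, charToRaw(" "))
    b
  }
  el_short <- function(group, elem, vr, bytes) {
    c(u16(group), u16(elem), charToRaw(vr), u16(length(bytes)), bytes)
  }
  el_long <- function(group, elem, vr, bytes) {
    c(u16(group), u16(elem), charToRaw(vr), as.raw(c(0, 0)),
      u32(length(bytes)), bytes)
  }
  meta_body <- c(
    el_short(2L, 2L, "UI", pad_even("1.2.840.10008.5.1.4.1.1.4")),
    el_short(2L, 3L, "UI", pad_even("1.2.3.4.5")),
    el_short(2L, 16L, "UI", pad_even("1.2.840.10008.1.2.1"))
  )
  meta <- c(el_short(2L, 0L, "UL", u32(length(meta_body))), meta_body)
  px <- t(pixels)  # row-major order
  pix_bytes <- if (bits_alloc == 16L) {
    writeBin(as.integer(px), raw(), size = 2L, endian = "little")
  } else {
    as.raw(px)
  }
  if (length(pix_bytes) %% 2L == 1L) pix_bytes <- c(pix_bytes, as.raw(0))
  body <- c(
    el_short(8L, 96L, "CS", pad_even("MR")),
    el_short(16L, 32L, "LO", pad_even(patient_id)),
    el_short(40L, 2L, "US", u16(1L)),
    el_short(40L, 4L, "CS", pad_even("MONOCHROME2")),
    el_short(40L, 16L, "US", u16(nrow(pixels))),
    el_short(40L, 17L, "US", u16(ncol(pixels))),
    if (!is.na(pixel_spacing)) {
      sp <- sprintf("%g\\%g", pixel_spacing, pixel_spacing)
      el_short(40L, 48L, "DS", pad_even(sp))
    },
    el_short(40L, 256L, "US", u16(bits_alloc)),
    el_short(40L, 257L, "US", u16(as.integer(bit_depth))),
    el_short(40L, 258L, "US", u16(as.integer(bit_depth) - 1L)),
    el_short(40L, 259L, "US", u16(0L)),
    el_long(32736L, 16L, "OW", pix_bytes)
  )
  out <- c(raw(128L), charToRaw("DICM"), meta, body)
  writeBin(out, path)
  invisible(path)
}
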