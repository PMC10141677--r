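#' Write a 16-bit grayscale PNG
#'
#' Minimal encoder for single-channel 16-bit PNG images (the container used
#' for the DICOM-like 12-bit renditions of synthetic scans). Pixel values
#' are stored verbatim as 16-bit big-endian samples, so a 12-bit image
#' round-trips exactly through [png::readPNG()] (which returns values
#' divided by 65535).
#'
#' @param pixels integer matrix, values in \[0, 65535\].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png16 <- function(pixels, path) {
  png_write_gray(pixels, path, 16L)
}

# shared grayscale PNG encoder: stores samples verbatim (no float
# quantization), bit depth 8 or 16
png_write_gray <- function(pixels, path, depth) {
  stopifnot(is.matrix(pixels), depth %in% c(8L, 16L))
  top <- 2^depth - 1
  v <- as.vector(pixels)
  if (anyNA(v) || any(v < 0) || any(v > top) || any(v != floor(v))) {
    stop("pixels must be integers in [0, ", top, "]")
  }
  h <- nrow(pixels)
  w <- ncol(pixels)
  ihdr <- c(png_u32(w), png_u32(h), as.raw(c(depth, 0L, 0L, 0L, 0L)))
  # scanlines: filter byte 0 + big-endian samples, image row-major
  px <- t(pixels)
  if (depth == 16L) {
    bytes <- matrix(0L, nrow = 1L + 2L * w, ncol = h)
    bytes[seq(2L, 2L * w, by = 2L), ] <- px %/% 256L
    bytes[seq(3L, 2L * w + 1L, by = 2L), ] <- px %% 256L
  } else {
    bytes <- rbind(0L, px)
  }
  dat <- memCompress(as.raw(bytes), type = "gzip")  # zlib stream
  out <- c(
    as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
    png_chunk("IHDR", ihdr),
    png_chunk("IDAT", dat),
    png_chunk("IEND", raw(0))
  )
  writeBin(out, path)
  invisible(path)
}

png_chunk <- function(type, data) {
  td <- c(charToRaw(type), data)
  c(png_u32(length(data)), td, png_u32(png_crc32(td)))
}

png_u32 <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
}

# CRC-32 with the register split into a high byte and a 24-bit low part.
# R integers cannot represent 0x80000000 (it is NA_integer_), so 32-bit
# bitwXor/bitwAnd chains sporadically produce NA on real data; the split
# keeps every intermediate strictly below 2^24.
png_crc32_table <- local({
  poly_hi <- 237L        # 0xEDB88320 >> 24
  poly_lo <- 12092192L   # 0xEDB88320 & 0xFFFFFF
  hi <- integer(256)
  lo <- integer(256)
  for (i in 0:255) {
    h <- 0L
    l <- i
    for (k in 1:8) {
      low_bit <- bitwAnd(l, 1L)
      l <- bitwShiftR(l, 1L) + bitwAnd(h, 1L) * 8388608L
      h <- bitwShiftR(h, 1L)
      if (low_bit == 1L) {
        h <- bitwXor(h, poly_hi)
        l <- bitwXor(l, poly_lo)
      }
    }
    hi[i + 1L] <- h
    lo[i + 1L] <- l
  }
  list(hi = hi, lo = lo)
})

png_crc32 <- function(bytes) {
  tab_hi <- png_crc32_table$hi
  tab_lo <- png_crc32_table$lo
  hi <- 255L
  lo <- 16777215L
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(lo, b), 255L) + 1L
    shifted <- hi * 65536L + bitwShiftR(lo, 8L)
    hi <- tab_hi[idx]
    lo <- bitwXor(tab_lo[idx], shifted)
  }
  # complement: subtracting from all-ones flips every bit
  4294967295 - (hi * 2^24 + lo)
}
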