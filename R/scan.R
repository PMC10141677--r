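#' Scan and region containers
#'
#' A `scan_image` is one 2-D grayscale MRI slice together with the metadata
#' the pipeline needs: integer pixel grid, stored bit depth (8 for PNG
#' renditions, 12 for DICOM), isotropic pixel spacing in mm, modality
#' (T1/T2), source format, patient identifier, and the integer age label in
#' years. A `region` is a rectangular crop of a scan that keeps the parent
#' scan's bit depth and provenance.
#'
#' @param pixels integer matrix (rows x cols) of intensities in
#'   \[0, 2^bit_depth - 1\].
#' @param bit_depth 8 or 12.
#' @param pixel_spacing mm per pixel, > 0 (may be `NA` when only
#'   pixel-mode ROIs will be used).
#' @param modality `"T1"` or `"T2"`.
#' @param source_format `"DICOM"` or `"PNG"`.
#' @param patient_id opaque identifier.
#' @param age_years integer age label.
#' @return an object of class `scan_image`.
#' @export
scan_image <- function(pixels, bit_depth, pixel_spacing = NA_real_,
                       modality = c("T1", "T2"),
                       source_format = c("DICOM", "PNG"),
                       patient_id = "anon", age_years = NA_integer_) {
  modality <- match.arg(modality)
  source_format <- match.arg(source_format)
  stopifnot(is.matrix(pixels), bit_depth %in% c(8L, 12L))
  L <- 2^bit_depth - 1
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > L) {
    stop("intensities must lie in [0, ", L, "] for bit depth ", bit_depth)
  }
  if (!is.na(pixel_spacing) && pixel_spacing <= 0) {
    stop("pixel_spacing must be positive")
  }
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         pixel_spacing = as.numeric(pixel_spacing), modality = modality,
         source_format = source_format, patient_id = patient_id,
         age_years = as.integer(age_years)),
    class = "scan_image"
  )
}

#' Read a wrist MRI slice from DICOM or PNG
#'
#' DICOM files carry bit depth and pixel spacing in their metadata; PNG
#' files carry neither a 12-bit depth marker nor any spacing, so the
#' spacing must be supplied (`pixel_spacing`) and a stored depth lower
#' than the container's can be declared with `bit_depth`. Intensities are
#' read verbatim (a DICOM rescale slope/intercept, if present, is applied
#' and rounded).
#'
#' @param path file path ending in `.dcm`/`.dicom` or `.png`.
#' @param age_years integer age label carried on the scan.
#' @param modality `"T1"` or `"T2"`.
#' @param patient_id identifier carried on the scan.
#' @param pixel_spacing mm per pixel; required for PNG, overrides DICOM
#'   metadata when given.
#' @param bit_depth stored bit depth override (e.g. 12 for a 12-bit image
#'   kept in a 16-bit PNG container); inferred from the file otherwise.
#' @return a [scan_image()].
#' @export
read_scan <- function(path, age_years = NA_integer_, modality = "T1",
                      patient_id = "anon", pixel_spacing = NULL,
                      bit_depth = NULL) {
  if (!file.exists(path)) stop("cannot read scan file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom")) {
    d <- read_dicom(path)
    spacing <- pixel_spacing %||% d$pixel_spacing
    depth <- bit_depth %||% d$bit_depth
    pixels <- d$pixels
    src <- "DICOM"
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (length(dim(img)) == 3L) {
      stop("unsupported format: color PNG (", dim(img)[3], " channels)")
    }
    container <- info$bit.depth
    depth <- bit_depth %||% container
    pixels <- matrix(round_half_away(img * (2^container - 1)),
                     nrow(img), ncol(img))
    if (is.null(pixel_spacing)) {
      stop("missing metadata: PNG carries no pixel spacing; supply pixel_spacing")
    }
    spacing <- pixel_spacing
    src <- "PNG"
  } else {
    stop("unsupported format: ", ext)
  }
  depth <- if (depth <= 8L) 8L else 12L
  scan_image(pixels, bit_depth = depth, pixel_spacing = spacing,
             modality = modality, source_format = src,
             patient_id = patient_id, age_years = age_years)
}

#' Write a scan or region to a grayscale PNG
#'
#' 8-bit images go to an 8-bit PNG via \pkg{png}; deeper images are stored
#' verbatim in a 16-bit container (see [write_png16()]), so values
#' round-trip exactly.
#'
#' @param x a [scan_image()], [region()] or plain integer matrix.
#' @param path output path.
#' @param bit_depth required when `x` is a plain matrix.
#' @return `path`, invisibly.
#' @export
write_scan_png <- function(x, path, bit_depth = NULL) {
  if (inherits(x, c("scan_image", "region"))) {
    bit_depth <- x$bit_depth
    pixels <- x$pixels
  } else {
    stopifnot(!is.null(bit_depth))
    pixels <- x
  }
  png_write_gray(pixels, path, if (bit_depth <= 8L) 8L else 16L)
  invisible(path)
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf(
    "<scan_image> %dx%d %s %s %d-bit, spacing %s mm, patient %s, age %s\n",
    nrow(x$pixels), ncol(x$pixels), x$source_format, x$modality,
    x$bit_depth, format(x$pixel_spacing), x$patient_id, x$age_years))
  invisible(x)
}
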