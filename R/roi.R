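#' Rectangular region-of-interest specifications
#'
#' An ROI is anchored at its top-left corner (0-based `(row, col)`) and
#' sized either in pixels or in millimetres (`size_mode = "metric"`). The
#' metric mode is how a cohort with heterogeneous pixel spacing keeps the
#' analysed patch physically constant: the extent in pixels is
#' `mm / pixel_spacing`, rounded half away from zero, never below 1.
#' Rectangles are half-open: `[row0, row0 + n_rows) x [col0, col0 + n_cols)`.
#'
#' @param region_kind `"bone"` (trabecular patch) or `"growth"` (growth
#'   plate band).
#' @param anchor_row,anchor_col 0-based top-left corner.
#' @param height,width extent in pixels or mm according to `size_mode`.
#' @param size_mode `"pixels"` or `"metric"`.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(region_kind = c("bone", "growth"), anchor_row, anchor_col,
                     height, width, size_mode = c("pixels", "metric")) {
  region_kind <- match.arg(region_kind)
  size_mode <- match.arg(size_mode)
  stopifnot(height > 0, width > 0, anchor_row >= 0, anchor_col >= 0)
  structure(
    list(region_kind = region_kind, anchor_row = as.integer(anchor_row),
         anchor_col = as.integer(anchor_col), height = height, width = width,
         size_mode = size_mode),
    class = "roi_spec"
  )
}

#' Resolve an ROI to a pixel rectangle on a scan
#'
#' @param spec a [roi_spec()].
#' @param scan a [scan_image()].
#' @return list `(row0, col0, n_rows, n_cols)`, 0-based half-open.
#' @export
resolve_roi <- function(spec, scan) {
  stopifnot(inherits(spec, "roi_spec"), inherits(scan, "scan_image"))
  if (spec$size_mode == "metric") {
    if (is.na(scan$pixel_spacing)) {
      stop("missing metadata: metric ROI needs a pixel spacing")
    }
    n_rows <- max(1L, as.integer(round_half_away(spec$height / scan$pixel_spacing)))
    n_cols <- max(1L, as.integer(round_half_away(spec$width / scan$pixel_spacing)))
  } else {
    n_rows <- as.integer(spec$height)
    n_cols <- as.integer(spec$width)
  }
  nr <- nrow(scan$pixels)
  nc <- ncol(scan$pixels)
  if (spec$anchor_row + n_rows > nr || spec$anchor_col + n_cols > nc) {
    stop(sprintf(
      "out of bounds: ROI [%d,%d)x[%d,%d) exceeds %dx%d scan",
      spec$anchor_row, spec$anchor_row + n_rows,
      spec$anchor_col, spec$anchor_col + n_cols, nr, nc))
  }
  list(row0 = spec$anchor_row, col0 = spec$anchor_col,
       n_rows = n_rows, n_cols = n_cols)
}

#' Crop a region from a scan
#'
#' The crop is an independent copy carrying the scan's bit depth, age
#' label, and provenance (patient, region kind, modality, source format).
#'
#' @inheritParams resolve_roi
#' @return an object of class `region`.
#' @export
extract_region <- function(scan, spec) {
  r <- resolve_roi(spec, scan)
  pixels <- scan$pixels[r$row0 + seq_len(r$n_rows),
                        r$col0 + seq_len(r$n_cols), drop = FALSE]
  structure(
    list(pixels = pixels, bit_depth = scan$bit_depth,
         patient_id = scan$patient_id, region_kind = spec$region_kind,
         modality = scan$modality, source_format = scan$source_format,
         age_years = scan$age_years),
    class = "region"
  )
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> %s %dx%d %d-bit (%s %s, patient %s, age %s)\n",
              x$region_kind, nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              x$source_format, x$modality, x$patient_id, x$age_years))
  invisible(x)
}
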