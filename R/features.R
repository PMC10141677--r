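#' Feature extraction configuration
#'
#' Bundles every tunable of the texture descriptor. The defaults are the
#' configuration used throughout this package: 64 quantized gray levels
#' for the matrix-based families, co-occurrence distances 1..5 and the
#' four axis/diagonal directions, Gabor envelopes 4/6/8/12/16/24, 8
#' orientation bins, 4 wavelet scales, and plus/minus-3-sigma
#' normalization applied before every family.
#'
#' @param levels gray levels G for co-occurrence/run-length quantization.
#' @param distances co-occurrence inter-pixel distances.
#' @param directions angles in degrees shared by the co-occurrence,
#'   run-length and Gabor families.
#' @param gabor_sizes Gabor envelope sizes (pixels).
#' @param hog_bins orientation bins of the gradient-orientation histogram.
#' @param n_scales dyadic wavelet scales.
#' @param normalize apply [normalize_3sigma()] before extraction.
#' @param ceiling_override optional normalization clamp ceiling (e.g. 255
#'   to force 12-bit input onto the 8-bit range).
#' @return a list of class `feature_config`.
#' @export
feature_config <- function(levels = 64L, distances = 1:5,
                           directions = c(0L, 45L, 90L, 135L),
                           gabor_sizes = c(4L, 6L, 8L, 12L, 16L, 24L),
                           hog_bins = 8L, n_scales = 4L, normalize = TRUE,
                           ceiling_override = NULL) {
  structure(
    list(levels = as.integer(levels), distances = as.integer(distances),
         directions = as.integer(directions),
         gabor_sizes = as.integer(gabor_sizes), hog_bins = as.integer(hog_bins),
         n_scales = as.integer(n_scales), normalize = isTRUE(normalize),
         ceiling_override = ceiling_override),
    class = "feature_config"
  )
}

glcm_stat_names <- c("asm", "contrast", "correlation", "sumofsqs", "idm",
                     "sumaverage", "sumvariance", "sumentropy", "entropy",
                     "diffvariance", "diffentropy")

#' Feature schema
#'
#' The fixed, ordered names of the descriptor for a given configuration.
#' With the defaults this is exactly 307 names: 9 histogram + 220
#' co-occurrence (11 statistics x 4 directions x 5 distances) + 20
#' run-length (5 x 4 directions) + 5 gradient + 5 autoregressive + 16
#' Haar energies (4 scales x 4 subbands) + 24 Gabor (4 directions x 6
#' envelopes) + 8 orientation-histogram bins.
#'
#' @param config a [feature_config()].
#' @return character vector of feature names.
#' @export
feature_schema <- function(config = feature_config()) {
  hist_names <- paste0("hist_", c("mean", "variance", "skewness", "kurtosis",
                                  "perc01", "perc10", "perc50", "perc90",
                                  "perc99"))
  glcm_names <- as.vector(outer_names(
    config$distances, config$directions,
    function(d, a) paste0("glcm_d", d, "_a", a, "_", glcm_stat_names)))
  rlm_names <- as.vector(vapply(
    config$directions,
    function(a) paste0("rlm_a", a, "_", c("sre", "lre", "gln", "rln", "rp")),
    character(5)))
  grad_names <- paste0("grad_", c("mean", "variance", "skewness", "kurtosis",
                                  "nonzero"))
  ar_names <- paste0("ar_", c("theta1", "theta2", "theta3", "theta4", "sigma"))
  haar_names <- as.vector(vapply(
    seq_len(config$n_scales),
    function(s) paste0("haar_s", s, "_", c("ll", "lh", "hl", "hh")),
    character(4)))
  gabor_names <- as.vector(vapply(
    config$gabor_sizes,
    function(s) sprintf("gabor_a%d_s%d", config$directions, s),
    character(length(config$directions))))
  hog_names <- paste0("hog_bin", seq_len(config$hog_bins))
  c(hist_names, glcm_names, rlm_names, grad_names, ar_names, haar_names,
    gabor_names, hog_names)
}

outer_names <- function(ds, as_, f) {
  unlist(lapply(ds, function(d) unlist(lapply(as_, function(a) f(d, a)))))
}

#' Extract the full texture descriptor of one region
#'
#' Applies plus/minus-3-sigma normalization (unless disabled in the
#' config), then evaluates every feature family on the normalized grid.
#' The result is a named numeric vector whose names and order follow
#' [feature_schema()] exactly and are identical for every region; with
#' the default configuration it has 307 entries, all finite (degenerate
#' inputs such as constant regions are handled by each family's
#' conventions rather than producing NaN).
#'
#' @param region a [region()], [normalize_3sigma()] output is accepted
#'   too, or a plain integer matrix (then `bit_depth` is required).
#' @param config a [feature_config()].
#' @param bit_depth for plain-matrix input.
#' @return named numeric vector (length 307 with defaults).
#' @export
extract_all <- function(region, config = feature_config(), bit_depth = NULL) {
  if (inherits(region, "region")) {
    bit_depth <- region$bit_depth
  } else if (is.matrix(region)) {
    if (is.null(bit_depth)) stop("bit_depth required for a plain matrix")
    region <- structure(list(pixels = region, bit_depth = bit_depth),
                        class = "region")
  }
  nr <- if (config$normalize) {
    normalize_3sigma(region, ceiling_override = config$ceiling_override)
  } else {
    list(pixels = region$pixels, L = config$ceiling_override %||%
           (2^bit_depth - 1))
  }
  px <- nr$pixels
  L <- nr$L
  with_family <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  q <- quantize_gray(px, L, config$levels)
  glcm_vals <- with_family("glcm", {
    unlist(lapply(config$distances, function(d) {
      unlist(lapply(config$directions, function(a) {
        glcm_features(glcm(q, a, d, config$levels))
      }))
    }))
  })
  rlm_vals <- with_family("rlm", {
    unlist(lapply(config$directions, function(a) {
      rlm_features(q, a, config$levels)
    }))
  })
  vals <- c(
    with_family("histogram", histogram_features(px)),
    glcm_vals,
    rlm_vals,
    with_family("gradient", gradient_features(px)),
    with_family("autoregressive", ar_features(px)),
    with_family("haar", haar_features(px, config$n_scales)),
    with_family("gabor",
                gabor_features(px, config$directions, config$gabor_sizes)),
    with_family("hog", hog_features(px, config$hog_bins))
  )
  names(vals) <- feature_schema(config)
  vals
}

#' Assemble a feature table from regions
#'
#' One row per region: the full descriptor plus provenance columns.
#'
#' @param regions list of [region()] objects.
#' @param config a [feature_config()].
#' @return a `feature_table`: list with `features` (matrix, rows =
#'   samples, columns = schema), `age_years`, `patient_id`, and a
#'   provenance data.frame.
#' @export
feature_table <- function(regions, config = feature_config()) {
  stopifnot(length(regions) > 0)
  feats <- t(vapply(regions, extract_all, config = config,
                    FUN.VALUE = numeric(length(feature_schema(config)))))
  prov <- data.frame(
    patient_id = vapply(regions, function(r) as.character(r$patient_id), ""),
    region_kind = vapply(regions, function(r) r$region_kind %||% NA_character_, ""),
    modality = vapply(regions, function(r) r$modality %||% NA_character_, ""),
    source_format = vapply(regions, function(r) r$source_format %||% NA_character_, ""),
    age_years = vapply(regions, function(r) as.integer(r$age_years), 1L),
    stringsAsFactors = FALSE
  )
  structure(
    list(features = feats, age_years = prov$age_years,
         patient_id = prov$patient_id, provenance = prov),
    class = "feature_table"
  )
}

#' Write a feature table to CSV
#'
#' Provenance columns first, then the 307 feature columns.
#'
#' @param table a [feature_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  df <- cbind(table$provenance, as.data.frame(table$features))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_csv()]
#'
#' @param path CSV path.
#' @return a `feature_table`.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  prov_cols <- c("patient_id", "region_kind", "modality", "source_format",
                 "age_years")
  feats <- as.matrix(df[, setdiff(names(df), prov_cols), drop = FALSE])
  structure(
    list(features = feats, age_years = as.integer(df$age_years),
         patient_id = as.character(df$patient_id),
         provenance = df[, prov_cols, drop = FALSE]),
    class = "feature_table"
  )
}
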