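#' Synthetic wrist-MRI cohort specification
#'
#' Describes a cohort of synthetic 512x512 coronal wrist scans with a
#' controlled, monotone age-to-texture relationship. Defaults emulate the
#' study conditions this pipeline targets: 30 patients contributing up to
#' three usable images each (55 in total), integer ages 9-17 with mean
#' about 12.4 and median 12, pixel spacings between 0.2539 and 0.3516 mm
#' with 0.293 mm the most common, T1/T2 contrast variants, and 12-bit
#' masters with derived 8-bit renditions.
#'
#' `effect_strength` scales every age dependency: at 0 the texture is
#' statistically independent of age; at 1 the full effect is present.
#'
#' @param n_patients number of patients (>= 4).
#' @param n_images total images; patients are topped up to at most
#'   `images_per_patient` each. `NULL` draws counts at random.
#' @param images_per_patient maximum usable images per patient (1..3).
#' @param age_range inclusive integer age range.
#' @param age_weights sampling weights per year of `age_range`.
#' @param effect_strength age-effect scaling in \[0, 1\].
#' @param pixel_spacing_set candidate spacings (mm).
#' @param pixel_spacing_weights sampling weights of the spacings.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 30L, n_images = 55L,
                        images_per_patient = 3L, age_range = c(9L, 17L),
                        age_weights = c(2, 4, 5, 6, 4, 3, 3, 2, 1),
                        effect_strength = 1,
                        pixel_spacing_set = c(0.2539, 0.2734, 0.293,
                                              0.3125, 0.3516),
                        pixel_spacing_weights = c(1, 1, 4, 1, 1),
                        seed = 1L) {
  ages <- seq(age_range[1], age_range[2])
  stopifnot(n_patients >= 4, images_per_patient >= 1, images_per_patient <= 3,
            length(age_weights) == length(ages),
            effect_strength >= 0, effect_strength <= 1,
            length(pixel_spacing_weights) == length(pixel_spacing_set))
  if (!is.null(n_images)) {
    stopifnot(n_images >= n_patients,
              n_images <= n_patients * images_per_patient)
  }
  structure(
    list(n_patients = as.integer(n_patients),
         n_images = if (!is.null(n_images)) as.integer(n_images),
         images_per_patient = as.integer(images_per_patient),
         ages = ages, age_weights = age_weights / sum(age_weights),
         effect_strength = effect_strength,
         pixel_spacing_set = pixel_spacing_set,
         pixel_spacing_weights =
           pixel_spacing_weights / sum(pixel_spacing_weights),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Age-dependent generator parameters. All age slopes are scaled by the
# effect strength; jitters are per-patient and age-independent. Units:
# band width in mm, intensities on the 12-bit scale, correlation length
# in pixels.
cohort_params <- function(age, effect, jit) {
  da <- age - 9
  list(
    band_width_mm = max(0.8, 3.5 - effect * 0.25 * da + jit$band_width),
    band_brightness = max(150, 1400 - effect * 120 * da + jit$band_brightness),
    # ongoing calcification: dark speckle inside the band grows with age
    band_speckle = max(0, effect * 0.09 * da + jit$band_speckle),
    bone_mean = 2400 - effect * 90 * da + jit$bone_mean,
    trab_amp = max(60, 350 + effect * 30 * da + jit$trab_amp),
    trab_corr_len = max(0.5, 2.8 - effect * 0.15 * da + jit$trab_corr_len)
  )
}

#' Generate a synthetic cohort
#'
#' Each image is a 512x512 12-bit master in two contrast renditions
#' (T1: growth band brighter than the marrow; T2: marrow bright, band
#' dark, i.e. band/marrow contrast inverted) built from shared structural
#' fields: smoothed Gaussian "marrow" background, a horizontal growth
#' band at the plate position whose width and brightness decrease with
#' age, and a trabecular slab of correlated noise whose correlation
#' length decreases and contrast increases with age. Bone and growth ROI
#' specifications (metric units, so the physical patch is constant across
#' pixel spacings) accompany every scan.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `synthetic_cohort`; elements are scans with
#'   `pixels_t1`, `pixels_t2` (integer 12-bit matrices), `pixel_spacing`,
#'   `patient_id`, `age_years`, ground-truth `params`, and `rois`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  np <- spec$n_patients
  ages <- sample(spec$ages, np, replace = TRUE, prob = spec$age_weights)
  spacing <- sample(spec$pixel_spacing_set, np, replace = TRUE,
                    prob = spec$pixel_spacing_weights)
  counts <- rep(1L, np)
  if (!is.null(spec$n_images)) {
    extra <- spec$n_images - np
    while (extra > 0L) {
      open <- which(counts < spec$images_per_patient)
      pick <- open[sample.int(length(open), 1L)]
      counts[pick] <- counts[pick] + 1L
      extra <- extra - 1L
    }
  } else {
    counts <- sample.int(spec$images_per_patient, np, replace = TRUE)
  }
  scans <- list()
  for (p in seq_len(np)) {
    jit <- list(band_width = stats::rnorm(1, 0, 0.12),
                band_brightness = stats::rnorm(1, 0, 30),
                band_speckle = stats::rnorm(1, 0, 0.04),
                bone_mean = stats::rnorm(1, 0, 45),
                trab_amp = stats::rnorm(1, 0, 15),
                trab_corr_len = stats::rnorm(1, 0, 0.08))
    par <- cohort_params(ages[p], spec$effect_strength, jit)
    pid <- sprintf("P%03d", p)
    for (img in seq_len(counts[p])) {
      scans[[length(scans) + 1L]] <-
        synth_scan(par, pid, ages[p], spacing[p])
    }
  }
  structure(scans, class = "synthetic_cohort")
}

# rows of the trabecular slab and the growth-plate band centre in the
# synthetic frame (the plate is transverse in a coronal wrist view)
SYNTH_SIZE <- 512L
BONE_ROWS <- 60:230
BAND_CENTER <- 256.5

synth_scan <- function(par, patient_id, age, spacing) {
  n <- SYNTH_SIZE
  unit_field <- function(sigma) {
    f <- blur_gaussian(matrix(stats::rnorm(n * n), n, n), sigma)
    f / stats::sd(f)
  }
  marrow <- unit_field(3)
  trab <- unit_field(par$trab_corr_len)
  band_tex <- unit_field(1.5)
  noise_t1 <- matrix(stats::rnorm(n * n, 0, 25), n, n)
  noise_t2 <- matrix(stats::rnorm(n * n, 0, 25), n, n)
  w_px <- par$band_width_mm / spacing
  band_profile <- exp(-(seq_len(n) - BAND_CENTER)^2 / (2 * (w_px / 2)^2))
  # calcified foci: thresholded correlated field -> dark dots whose area
  # fraction grows with par$band_speckle
  speckle <- (band_tex < stats::qnorm(min(0.9, par$band_speckle))) * 1
  band <- band_profile * matrix(1, n, n) *
    (1 + 0.15 * band_tex) * (1 - 0.85 * speckle)
  compose <- function(marrow_base, bone_base, band_amp, noise) {
    img <- marrow_base + 150 * marrow
    img[BONE_ROWS, ] <- bone_base + par$trab_amp * trab[BONE_ROWS, ]
    img <- img + band_amp * band + noise
    m <- matrix(as.integer(round_half_away(pmin(pmax(img, 0), 4095))), n, n)
    m
  }
  t1 <- compose(1800, par$bone_mean, par$band_brightness, noise_t1)
  t2 <- compose(2600, 0.6 * par$bone_mean, -0.8 * par$band_brightness,
                noise_t2)
  list(
    pixels_t1 = t1, pixels_t2 = t2, pixel_spacing = spacing,
    patient_id = patient_id, age_years = as.integer(age), params = par,
    rois = list(
      bone = roi_spec("bone", anchor_row = 100, anchor_col = 232,
                      height = 14.06, width = 14.06, size_mode = "metric"),
      growth = roi_spec("growth", anchor_row = 232, anchor_col = 232,
                        height = 14.06, width = 14.06, size_mode = "metric")
    )
  )
}

# per-image min-max rescale of a 12-bit master to the 8-bit range,
# mirroring how the PNG renditions of the original data were produced
to_8bit <- function(pixels) {
  lo <- min(pixels)
  hi <- max(pixels)
  if (hi == lo) return(matrix(0L, nrow(pixels), ncol(pixels)))
  matrix(as.integer(round_half_away((pixels - lo) / (hi - lo) * 255)),
         nrow(pixels), ncol(pixels))
}

#' Turn a synthetic cohort into a feature table
#'
#' Selects the requested rendition of every scan (modality and bit
#' depth; the 8-bit rendition is the per-image min-max rescale of the
#' 12-bit master), crops the requested ROI, and extracts the full
#' descriptor. For the growth region only the first image of each
#' patient is used, reproducing the study design in which the growth
#' plate was analysed on one image per patient.
#'
#' @param cohort a [generate_cohort()] result.
#' @param roi_kind `"bone"` or `"growth"`.
#' @param modality `"T1"` or `"T2"`.
#' @param bit_depth 12 (master) or 8 (PNG-like rendition).
#' @param config a [feature_config()].
#' @return a [feature_table()].
#' @export
cohort_to_feature_table <- function(cohort, roi_kind = c("bone", "growth"),
                                    modality = c("T1", "T2"), bit_depth = 12L,
                                    config = feature_config()) {
  roi_kind <- match.arg(roi_kind)
  modality <- match.arg(modality)
  stopifnot(bit_depth %in% c(8L, 12L))
  scans <- cohort
  if (roi_kind == "growth") {
    first <- !duplicated(vapply(cohort, function(s) s$patient_id, ""))
    scans <- cohort[first]
  }
  regions <- lapply(scans, function(s) {
    px <- if (modality == "T1") s$pixels_t1 else s$pixels_t2
    if (bit_depth == 8L) px <- to_8bit(px)
    sc <- scan_image(px, bit_depth = bit_depth,
                     pixel_spacing = s$pixel_spacing, modality = modality,
                     source_format = if (bit_depth == 12L) "DICOM" else "PNG",
                     patient_id = s$patient_id, age_years = s$age_years)
    extract_region(sc, s$rois[[roi_kind]])
  })
  feature_table(regions, config)
}

#' Write a synthetic cohort to disk
#'
#' One DICOM file (12-bit master) and one 8-bit PNG rendition per scan
#' and modality, a manifest CSV (path, patient_id, age_years, modality,
#' bit_depth, pixel_spacing), and an ROI configuration CSV — the same
#' shape of inputs the extraction stage consumes for real data.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    for (mod in c("T1", "T2")) {
      px <- if (mod == "T1") s$pixels_t1 else s$pixels_t2
      base <- sprintf("scan%03d_%s", i, mod)
      dcm <- file.path(dir, paste0(base, ".dcm"))
      write_dicom(px, dcm, bit_depth = 12L, pixel_spacing = s$pixel_spacing,
                  patient_id = s$patient_id)
      png8 <- file.path(dir, paste0(base, "_8bit.png"))
      png_write_gray(to_8bit(px), png8, 8L)
      rows[[length(rows) + 1L]] <- data.frame(
        path = c(dcm, png8), patient_id = s$patient_id,
        age_years = s$age_years, modality = mod, bit_depth = c(12L, 8L),
        pixel_spacing = s$pixel_spacing)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  r <- cohort[[1]]$rois
  roi_df <- do.call(rbind, lapply(r, function(x) {
    data.frame(region_kind = x$region_kind, anchor_row = x$anchor_row,
               anchor_col = x$anchor_col, height = x$height, width = x$width,
               size_mode = x$size_mode)
  }))
  utils::write.csv(roi_df, file.path(dir, "roi_config.csv"), row.names = FALSE)
  invisible(manifest_path)
}
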