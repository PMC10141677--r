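test_that("cohort generation is bit-identical under a fixed seed", {
  s1 <- generate_cohort(test_cohort_spec(seed = 71))
  s2 <- generate_cohort(test_cohort_spec(seed = 71))
  expect_identical(s1, s2)
  s3 <- generate_cohort(test_cohort_spec(seed = 72))
  expect_false(identical(s1[[1]]$pixels_t1, s3[[1]]$pixels_t1))
  # integer 12-bit pixels, both contrasts
  expect_true(is.integer(s1[[1]]$pixels_t1))
  expect_equal(dim(s1[[1]]$pixels_t1), c(512L, 512L))
  expect_true(all(s1[[1]]$pixels_t1 >= 0 & s1[[1]]$pixels_t1 <= 4095))
  expect_true(all(s1[[1]]$pixels_t2 >= 0 & s1[[1]]$pixels_t2 <= 4095))
})

test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(n_patients = 3), "n_patients")
  expect_error(cohort_spec(effect_strength = 1.5), "effect_strength")
  expect_error(cohort_spec(n_patients = 10, n_images = 40,
                           images_per_patient = 3))
  sp <- cohort_spec()
  expect_equal(sum(sp$age_weights), 1)
  expect_equal(sp$ages, 9:17)
})

test_that("feature tables from a cohort have the study shapes and no gaps", {
  co <- generate_cohort(test_cohort_spec(seed = 73, n_patients = 5,
                                         n_images = 9))
  tb <- cohort_to_feature_table(co, "bone", "T1", 12L)
  expect_equal(dim(tb$features), c(9L, 307L))
  expect_false(anyNA(tb$features))
  expect_true(all(is.finite(tb$features)))
  # growth region: first image of each patient only
  tg <- cohort_to_feature_table(co, "growth", "T2", 8L)
  expect_equal(dim(tg$features), c(5L, 307L))
  expect_equal(anyDuplicated(tg$patient_id), 0L)
})

test_that("growth-band brightness decreases with age at full effect", {
  co <- generate_cohort(cohort_spec(n_patients = 20L, n_images = 30L,
                                    seed = 74))
  ages <- vapply(co, function(s) s$age_years, 1L)
  bright <- vapply(co, function(s) s$params$band_brightness, 1.0)
  by_age <- tapply(bright, ages, mean)
  expect_true(all(diff(by_age) < 0))
  w <- vapply(co, function(s) s$params$band_width_mm, 1.0)
  expect_lt(stats::cor(ages, w), -0.5)
})

test_that("at zero effect strength the texture is independent of age", {
  co <- generate_cohort(cohort_spec(n_patients = 12L, n_images = 20L,
                                    effect_strength = 0, seed = 75))
  tb <- cohort_to_feature_table(co, "bone", "T1", 12L)
  X <- tb$features[, apply(tb$features, 2, stats::sd) > 0]
  y <- tb$age_years
  rho <- abs(suppressWarnings(stats::cor(X, y, method = "spearman")))
  # global permutation test on the strongest association: under
  # independence the observed max |rho| is unremarkable among permuted
  # maxima (family-wise p-value well above any rejection level)
  set.seed(76)
  B <- 200
  perms <- replicate(B, sample(y))
  null_rho <- abs(suppressWarnings(stats::cor(X, perms, method = "spearman")))
  p_global <- mean(apply(null_rho, 2, max) >= max(rho))
  expect_gt(p_global, 0.05)
})

test_that("written cohorts are re-readable through the manifest", {
  co <- generate_cohort(test_cohort_spec(seed = 77, n_patients = 4,
                                         n_images = 4))
  dir <- file.path(tempdir(), "cohort-test")
  write_cohort(co, dir)
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 4 * 4)  # 4 scans x 2 modalities x 2 renditions
  row <- man[man$bit_depth == 12 & man$modality == "T1", ][1, ]
  s <- read_scan(row$path, age_years = row$age_years, modality = row$modality,
                 patient_id = row$patient_id)
  expect_equal(s$pixels, co[[1]]$pixels_t1)
  expect_equal(s$pixel_spacing, co[[1]]$pixel_spacing)
  roi <- utils::read.csv(file.path(dir, "roi_config.csv"))
  expect_setequal(roi$region_kind, c("bone", "growth"))
  unlink(dir, recursive = TRUE)
})
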