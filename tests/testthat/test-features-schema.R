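test_that("the descriptor has exactly 307 features with the stated family sizes", {
  sch <- feature_schema()
  expect_length(sch, 307)
  fam <- table(sub("_.*", "", sch))
  expect_equal(fam[["hist"]], 9)
  expect_equal(fam[["glcm"]], 220)   # 11 statistics x 4 directions x 5 distances
  expect_equal(fam[["rlm"]], 20)     # 5 statistics x 4 directions
  expect_equal(fam[["grad"]], 5)
  expect_equal(fam[["ar"]], 5)
  expect_equal(fam[["haar"]], 16)    # 4 scales x 4 subbands
  expect_equal(fam[["gabor"]], 24)   # 4 directions x 6 envelopes
  expect_equal(fam[["hog"]], 8)
  expect_false(anyDuplicated(sch) > 0)
})

test_that("extraction is deterministic, schema-stable, and finite everywhere", {
  set.seed(41)
  r1 <- as_region(matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64))
  r2 <- as_region(matrix(sample(0:4095, 48 * 48, replace = TRUE), 48, 48),
                  bit_depth = 12L)
  v1 <- extract_all(r1)
  v2 <- extract_all(r2)
  expect_identical(names(v1), feature_schema())
  expect_identical(names(v1), names(v2))
  expect_true(all(is.finite(v1)))
  expect_true(all(is.finite(v2)))
  expect_identical(v1, extract_all(r1))  # bit-identical re-extraction

  # constant region: still 307 finite values
  vc <- extract_all(as_region(matrix(7L, 32, 32)))
  expect_length(vc, 307)
  expect_true(all(is.finite(vc)))
})

test_that("family errors carry the family name, and small regions fail cleanly", {
  tiny <- as_region(matrix(sample(0:255, 64, replace = TRUE), 8, 8))
  expect_error(extract_all(tiny), "haar|gabor")
})

test_that("feature tables export and re-import through CSV losslessly enough", {
  set.seed(42)
  regs <- lapply(1:4, function(i) {
    as_region(matrix(sample(0:255, 48 * 48, replace = TRUE), 48, 48),
              patient_id = sprintf("P%02d", i), region_kind = "bone",
              modality = "T1", source_format = "PNG",
              age_years = 9L + i)
  })
  tab <- feature_table(regs)
  expect_equal(dim(tab$features), c(4L, 307L))
  expect_equal(tab$age_years, 10:13)
  f <- tempfile(fileext = ".csv")
  write_feature_csv(tab, f)
  back <- read_feature_csv(f)
  expect_equal(colnames(back$features), colnames(tab$features))
  expect_equal(back$features, tab$features, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$age_years, tab$age_years)
})
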