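test_that("normalization maps the 3-sigma window onto [0, L] with clamping", {
  # 20 values with mean exactly 100 and population sd exactly 10:
  # {130, 70, 110, 90, 16 x 100}; min_norm = 70, max_norm = 130
  px <- matrix(c(130, 70, 110, 90, rep(100, 16)), 4, 5)
  n <- normalize_3sigma(px, bit_depth = 8L)
  expect_equal(n$mu, 100)
  expect_equal(n$sigma, 10)
  expect_equal(n$min_norm, 70)
  expect_equal(n$max_norm, 130)
  expect_equal(n$pixels[1, 1], 255)  # value at max_norm -> L
  expect_equal(n$pixels[2, 1], 0)    # value at min_norm -> 0
  expect_equal(n$pixels[3, 1], 170)  # 255 * (110-70)/60
  expect_equal(n$pixels[4, 1], 85)   # 255 * (90-70)/60
  expect_equal(n$pixels[1, 2], 128)  # mid-gray, half rounds away from zero

  # 24 values with mean 100 and sd 10 containing 140 (> max_norm):
  # {140, 80, 80, 21 x 100}; 140 clamps to 255
  px2 <- matrix(c(140, 80, 80, rep(100, 21)), 4, 6)
  n2 <- normalize_3sigma(px2, bit_depth = 8L)
  expect_equal(n2$sigma, 10)
  expect_equal(n2$pixels[1, 1], 255)
})

test_that("normalization agrees with direct equation evaluation on random regions", {
  set.seed(101)
  for (k in 1:50) {
    bd <- sample(c(8L, 12L), 1)
    L <- 2^bd - 1
    px <- matrix(sample(0:L, 64, replace = TRUE), 8, 8)
    got <- normalize_3sigma(px, bit_depth = bd)
    expect_equal(got$pixels, bf_normalize(px, L))
    expect_true(all(got$pixels >= 0 & got$pixels <= L))
    expect_equal(got$min_norm, got$mu - 3 * got$sigma)
    expect_equal(got$max_norm, got$mu + 3 * got$sigma)
  }
})

test_that("normalization is monotone and affine-invariant up to rounding", {
  set.seed(102)
  px <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  n1 <- normalize_3sigma(px, bit_depth = 8L)
  # monotone: sort order of intensities is preserved
  o <- order(as.vector(px))
  expect_true(all(diff(as.vector(n1$pixels)[o]) >= 0))
  # affine invariance: a*I + b yields the same output within 1 gray level
  px2 <- 3 * px + 40
  n2 <- normalize_3sigma(px2, bit_depth = 12L)  # wider range to avoid clipping
  n2b <- normalize_3sigma(px, bit_depth = 12L)
  expect_lte(max(abs(n2$pixels - n2b$pixels)), 1)
})

test_that("constant regions normalize to mid-gray, and 12-bit uses L = 4095", {
  n <- normalize_3sigma(matrix(7, 5, 5), bit_depth = 8L)
  expect_true(all(n$pixels == 128))
  n12 <- normalize_3sigma(matrix(7, 5, 5), bit_depth = 12L)
  expect_true(all(n12$pixels == 2048))
  # 12-bit clamp ceiling is 4095 unless overridden
  px <- matrix(sample(0:4095, 256, replace = TRUE), 16, 16)
  expect_equal(normalize_3sigma(px, bit_depth = 12L)$L, 4095)
  expect_equal(normalize_3sigma(px, bit_depth = 12L,
                                ceiling_override = 255)$L, 255)
})

test_that("data spanning exactly the 3-sigma window is idempotent up to rounding", {
  set.seed(103)
  px <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  once <- normalize_3sigma(px, bit_depth = 8L)$pixels
  twice <- normalize_3sigma(once, bit_depth = 8L)$pixels
  thrice <- normalize_3sigma(twice, bit_depth = 8L)$pixels
  expect_lte(max(abs(thrice - twice)), 2)
})
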