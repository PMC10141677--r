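test_that("co-occurrence matrix matches hand-worked cases", {
  # 2x2 grid [[0,1],[0,1]]: horizontal d=1 pairs are (0,1) twice
  q <- matrix(c(0L, 1L, 0L, 1L), 2, 2, byrow = TRUE)
  P <- glcm(q, 0, 1, 2)
  expect_equal(P, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(glcm_features(P)[["contrast"]], 1)

  # checkerboard, horizontal d=2: only equal-level pairs
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2L)
  P2 <- glcm(cb, 0, 2, 2)
  expect_equal(sum(diag(P2)), 1)

  # single-cell matrix: ASM 1, entropy 0, contrast 0
  const <- glcm(matrix(3L, 4, 4), 45, 1, 8)
  f <- glcm_features(const)
  expect_equal(f[["asm"]], 1)
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["contrast"]], 0)

  # too-small region for the offset
  expect_error(glcm(matrix(0L, 2, 2), 90, 3, 2), "insufficient extent")
})

test_that("co-occurrence matrices are symmetric, normalized and match brute force", {
  set.seed(11)
  for (k in 1:60) {
    levels <- sample(2:4, 1)
    q <- random_grid(sample(3:8, 1), sample(3:8, 1), levels)
    d <- sample(1:2, 1)
    for (a in c(0, 45, 90, 135)) {
      P <- glcm(q, a, d, levels)
      expect_equal(sum(P), 1)
      expect_equal(P, t(P))
      expect_equal(P, bf_glcm(q, a, d, levels), tolerance = 1e-12)
      expect_equal(glcm_features(P), bf_glcm_stats(P), tolerance = 1e-12)
    }
  }
})

test_that("run-length features match hand-worked cases", {
  # single row [0,0,1,1,1]: runs (0,len2) and (1,len3)
  r <- matrix(c(0L, 0L, 1L, 1L, 1L), 1, 5)
  f <- rlm_features(r, 0, 2)
  expect_equal(f[["sre"]], (1 / 4 + 1 / 9) / 2)
  expect_equal(f[["lre"]], (4 + 9) / 2)
  expect_equal(f[["rp"]], 2 / 5)

  # constant region: one run per row horizontally
  cr <- matrix(5L, 4, 7)
  fc <- rlm_features(cr, 0, 8)
  expect_equal(fc[["lre"]], 49)       # n_cols^2
  expect_equal(fc[["rp"]], 4 / 28)    # runs / pixels

  # checkerboard: all runs length 1
  cb <- outer(1:5, 1:6, function(i, j) (i + j) %% 2L)
  expect_equal(rlm_features(cb, 0, 2)[["sre"]], 1)
  expect_equal(rlm_features(cb, 0, 2)[["lre"]], 1)
})

test_that("run-length matrices match brute-force line walking in all directions", {
  set.seed(12)
  for (k in 1:60) {
    levels <- sample(2:4, 1)
    q <- random_grid(sample(3:8, 1), sample(3:8, 1), levels)
    for (a in c(0, 45, 90, 135)) {
      M <- run_length_matrix(q, a, levels)
      B <- bf_rlm(q, a, levels)
      expect_equal(unname(M[, seq_len(ncol(B)), drop = FALSE]),
                   unname(B), tolerance = 1e-12)
      # every pixel is covered by exactly one run
      expect_equal(sum(M %*% seq_len(ncol(M))), length(q))
      expect_equal(rlm_stats(M, length(q)), bf_rlm_stats(M, length(q)),
                   tolerance = 1e-12)
    }
  }
})

test_that("quantization partitions [0, L] uniformly", {
  expect_equal(quantize_gray(matrix(c(0, 63, 64, 255), 2, 2), 255, 4),
               matrix(c(0L, 0L, 1L, 3L), 2, 2))
  expect_equal(range(quantize_gray(matrix(0:4095, 64, 64), 4095, 64)),
               c(0L, 63L))
})
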