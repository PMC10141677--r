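test_that("histogram features match definition formulas and ignore spatial order", {
  f <- histogram_features(matrix(c(0, 0, 255, 255), 2, 2))
  expect_equal(f[["mean"]], 127.5)
  expect_equal(f[["variance"]], 16256.25)   # population variance
  expect_equal(f[["perc50"]], 127.5)        # type-7 median

  fc <- histogram_features(matrix(10, 3, 3))
  expect_equal(fc[["mean"]], 10)
  expect_equal(fc[["variance"]], 0)
  expect_equal(fc[["skewness"]], 0)
  expect_equal(fc[["kurtosis"]], 0)
  expect_true(all(fc[c("perc01", "perc10", "perc50", "perc90", "perc99")] == 10))

  set.seed(21)
  px <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  expect_equal(histogram_features(px),
               histogram_features(px[sample(8), , drop = FALSE]))
})

test_that("gradient features vanish on constants and ignore DC offsets", {
  fc <- gradient_features(matrix(42, 5, 5))
  expect_equal(fc[["mean"]], 0)
  expect_equal(fc[["variance"]], 0)
  expect_equal(fc[["nonzero"]], 0)

  set.seed(22)
  px <- matrix(sample(0:200, 100, replace = TRUE), 10, 10)
  expect_equal(gradient_features(px), gradient_features(px + 55))

  # vertical step edge: response confined to the two interior columns
  # adjacent to the edge
  step <- cbind(matrix(0, 8, 4), matrix(100, 8, 4))
  fs <- gradient_features(step)
  expect_equal(fs[["nonzero"]], (2 * 6) / (6 * 6))

  expect_error(gradient_features(matrix(0, 2, 5)), "insufficient extent")
})

test_that("autoregressive features recover a known causal field", {
  expect_equal(ar_features(matrix(9, 6, 6))[["sigma"]], 0)

  # I(., col) = 0.5 * I(., col-1) + N(0,1): left-neighbour weight 0.5
  set.seed(23)
  n <- 80
  m <- matrix(0, n, n)
  m[, 1] <- rnorm(n)
  for (cc in 2:n) m[, cc] <- 0.5 * m[, cc - 1] + rnorm(n)
  th <- ar_features(m)
  expect_lt(abs(th[["theta1"]] - 0.5), 0.05)
  expect_lt(max(abs(th[c("theta2", "theta3", "theta4")])), 0.05)
  expect_lt(abs(th[["sigma"]] - 1), 0.1)

  # least squares: residuals orthogonal to the regressors
  set.seed(24)
  px <- matrix(sample(0:255, 144, replace = TRUE), 12, 12)
  f <- ar_features(px)
  mm <- px - mean(px)
  i <- 2:12; j <- 2:11
  y <- as.vector(mm[i, j])
  X <- cbind(as.vector(mm[i, j - 1]), as.vector(mm[i - 1, j - 1]),
             as.vector(mm[i - 1, j]), as.vector(mm[i - 1, j + 1]))
  res <- y - X %*% f[1:4]
  expect_lt(max(abs(crossprod(X, res))), 1e-6)
})

test_that("orientation histogram is magnitude-weighted, normalized, ramp-aligned", {
  expect_true(all(hog_features(matrix(3, 6, 6)) == 0))

  # left-to-right ramp: gradient along +col (0 degrees) -> all mass in bin 1
  ramp <- outer(rep(1, 8), 1:8) * 10
  h <- hog_features(ramp)
  expect_equal(h[["bin1"]], 1)
  expect_equal(sum(h), 1)

  set.seed(25)
  px <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  expect_equal(sum(hog_features(px)), 1)
  expect_true(all(hog_features(px) >= 0))
})
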