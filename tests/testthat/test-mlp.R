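test_that("perceptron training is deterministic given the seed", {
  set.seed(51)
  X <- matrix(rnorm(120), 40, 3)
  y <- X[, 1] - 2 * X[, 2] + rnorm(40, sd = 0.1)
  f1 <- mlp_fit(X, y, seed = 9)
  f2 <- mlp_fit(X, y, seed = 9)
  expect_identical(predict(f1, X), predict(f2, X))
  f3 <- mlp_fit(X, y, seed = 10)
  expect_false(identical(predict(f1, X), predict(f3, X)))
})

test_that("perceptron fits a constant and a noiseless linear target", {
  set.seed(52)
  X <- matrix(rnorm(150), 50, 3)
  fc <- mlp_fit(X, rep(11, 50), seed = 1)
  expect_lt(max(abs(predict(fc, X) - 11)), 0.1)

  y <- 2 * X[, 1]
  fl <- mlp_fit(X, y, seed = 1, l2 = 0)
  expect_lt(mean(abs(predict(fl, X) - y)), 0.1)
})

test_that("perceptron rejects non-finite inputs and restores the RNG stream", {
  X <- matrix(c(1, NA, 2, 3), 2, 2)
  expect_error(mlp_fit(X, c(1, 2)), "non-finite")

  set.seed(53)
  Xr <- matrix(rnorm(30), 10, 3)
  yr <- rnorm(10)
  before <- .Random.seed
  invisible(mlp_fit(Xr, yr, seed = 4))
  expect_identical(.Random.seed, before)
})
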