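#' First-order histogram features
#'
#' Nine statistics of the intensity distribution, ignoring spatial
#' arrangement: mean, population variance, skewness, excess kurtosis, and
#' the 1st, 10th, 50th, 90th and 99th percentiles (type-7 quantiles).
#' Skewness and kurtosis of a constant region are defined as 0.
#'
#' @param pixels integer matrix of intensities.
#' @return named numeric vector of 9 values.
#' @export
histogram_features <- function(pixels) {
  v <- as.vector(pixels)
  m <- moment_stats(v)
  q <- stats::quantile(v, probs = c(0.01, 0.10, 0.50, 0.90, 0.99),
                       names = FALSE, type = 7)
  c(mean = unname(m["mean"]), variance = unname(m["variance"]),
    skewness = unname(m["skewness"]), kurtosis = unname(m["kurtosis"]),
    perc01 = q[1], perc10 = q[2], perc50 = q[3], perc90 = q[4], perc99 = q[5])
}

#' Gradient-magnitude features
#'
#' A 3x3 Laplacian high-pass mask (`4c - up - down - left - right`) is
#' applied to the interior of the region; the absolute response is the
#' gradient-magnitude map. Features: mean, population variance, skewness,
#' excess kurtosis of the map, and the fraction of interior pixels with a
#' nonzero response. Adding a constant to the region leaves all five
#' unchanged (the mask has zero DC gain).
#'
#' @param pixels integer matrix, at least 3x3.
#' @return named numeric vector of 5 values.
#' @export
gradient_features <- function(pixels) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  if (nr < 3 || nc < 3) stop("insufficient extent: gradient needs >= 3x3")
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  lap <- 4 * pixels[i, j, drop = FALSE] -
    pixels[i - 1, j, drop = FALSE] - pixels[i + 1, j, drop = FALSE] -
    pixels[i, j - 1, drop = FALSE] - pixels[i, j + 1, drop = FALSE]
  mag <- abs(lap)
  m <- moment_stats(as.vector(mag))
  c(mean = unname(m["mean"]), variance = unname(m["variance"]),
    skewness = unname(m["skewness"]), kurtosis = unname(m["kurtosis"]),
    nonzero = mean(mag != 0))
}

#' First-order causal autoregressive features
#'
#' Models each interior pixel (after subtracting the region mean) as a
#' weighted sum of its four causal neighbours — left, upper-left, upper,
#' upper-right — fitted by least squares over the region. Features are
#' the four weights theta1..theta4 and the residual root-mean-square
#' sigma. A rank-deficient design (e.g. a constant region) takes the
#' minimum-norm solution, giving sigma = 0 for exactly predictable
#' regions.
#'
#' @param pixels numeric matrix, at least 3x3.
#' @return named numeric vector `theta1..theta4`, `sigma`.
#' @export
ar_features <- function(pixels) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  if (nr < 3 || nc < 3) stop("insufficient extent: AR model needs >= 3x3")
  m <- pixels - mean(pixels)
  i <- 2:nr; j <- 2:(nc - 1)
  y <- as.vector(m[i, j, drop = FALSE])
  X <- cbind(
    left       = as.vector(m[i, j - 1, drop = FALSE]),
    upper_left = as.vector(m[i - 1, j - 1, drop = FALSE]),
    upper      = as.vector(m[i - 1, j, drop = FALSE]),
    upper_right = as.vector(m[i - 1, j + 1, drop = FALSE])
  )
  sv <- svd(X)
  tol <- max(dim(X)) * max(sv$d, 0) * .Machine$double.eps
  pos <- sv$d > tol
  theta <- if (any(pos)) {
    sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  } else {
    matrix(0, 4, 1)
  }
  res <- y - X %*% theta
  c(theta1 = theta[1], theta2 = theta[2], theta3 = theta[3],
    theta4 = theta[4], sigma = sqrt(mean(res^2)))
}

#' Histogram of oriented gradients
#'
#' Central-difference gradients on the interior of the region; the
#' orientation `atan2(gy, gx)` is binned into 8 equal sectors of
#' \[0, 360) degrees (bin 1 starts at 0 degrees, the +col direction),
#' weighted by gradient magnitude, and normalized to sum to 1. A region
#' with no gradient anywhere returns all zeros.
#'
#' @param pixels integer matrix, at least 3x3.
#' @param bins number of orientation bins (8 in this pipeline).
#' @return numeric vector `bin1..bin8`, summing to 1 (or all 0).
#' @export
hog_features <- function(pixels, bins = 8L) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  if (nr < 3 || nc < 3) stop("insufficient extent: HOG needs >= 3x3")
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  gx <- (pixels[i, j + 1, drop = FALSE] - pixels[i, j - 1, drop = FALSE]) / 2
  gy <- (pixels[i + 1, j, drop = FALSE] - pixels[i - 1, j, drop = FALSE]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% (2 * pi)
  bin <- pmin(floor(ang / (2 * pi / bins)), bins - 1) + 1
  h <- numeric(bins)
  keep <- mag > 0
  if (any(keep)) {
    h <- as.vector(tapply(mag[keep], factor(bin[keep], levels = seq_len(bins)),
                          sum, default = 0))
    h <- h / sum(h)
  }
  names(h) <- paste0("bin", seq_len(bins))
  h
}
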