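#' Round half away from zero
#'
#' Deterministic rounding used throughout the package (metric-to-pixel ROI
#' conversion, intensity normalization): halves round away from zero on
#' every platform, unlike [base::round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Population moments of a numeric vector
#'
#' Mean, population variance, skewness and excess kurtosis. When the
#' variance is zero, skewness and kurtosis are defined as 0 rather than
#' NaN so that constant regions yield finite features.
#'
#' @param x numeric vector.
#' @return named numeric vector `mean`, `variance`, `skewness`, `kurtosis`.
#' @keywords internal
moment_stats <- function(x) {
  n <- length(x)
  mu <- mean(x)
  d <- x - mu
  v <- mean(d^2)
  if (v > 0) {
    sk <- mean(d^3) / v^1.5
    ku <- mean(d^4) / v^2 - 3
  } else {
    sk <- 0
    ku <- 0
  }
  c(mean = mu, variance = v, skewness = sk, kurtosis = ku)
}

# Separable Gaussian blur with circular (wrap-around) boundaries, done in
# the frequency domain. Used by the synthetic generator to create
# correlated noise fields; wrap-around seams never intersect the ROIs.
blur_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  n <- nrow(m)
  p <- ncol(m)
  kr <- wrapped_gaussian(n, sigma)
  kc <- wrapped_gaussian(p, sigma)
  K <- outer(stats::fft(kr), stats::fft(kc))
  Re(stats::fft(stats::fft(m) * K, inverse = TRUE)) / (n * p)
}

wrapped_gaussian <- function(n, sigma) {
  h <- min(n %/% 2, ceiling(4 * sigma))
  g <- stats::dnorm(seq(-h, h), sd = sigma)
  g <- g / sum(g)
  k <- numeric(n)
  idx <- ((seq(-h, h)) %% n) + 1L
  for (i in seq_along(idx)) k[idx[i]] <- k[idx[i]] + g[i]
  k
}

# 2-D linear convolution via FFT, returning the "same"-size response for a
# centred (2h+1)x(2h+1) kernel; the input is reflection-padded by h so the
# response is defined up to the region border.
conv2_same <- function(m, kernel) {
  kh <- (nrow(kernel) - 1L) %/% 2L
  kw <- (ncol(kernel) - 1L) %/% 2L
  mp <- pad_reflect(m, kh, kw)
  n <- nrow(mp) + nrow(kernel) - 1L
  p <- ncol(mp) + ncol(kernel) - 1L
  A <- matrix(0, n, p); A[seq_len(nrow(mp)), seq_len(ncol(mp))] <- mp
  B <- matrix(0, n, p); B[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (n * p)
  r0 <- 2L * kh; c0 <- 2L * kw
  full[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m)), drop = FALSE]
}

pad_reflect <- function(m, kh, kw) {
  n <- nrow(m); p <- ncol(m)
  ri <- reflect_index(seq(1L - kh, n + kh), n)
  ci <- reflect_index(seq(1L - kw, p + kw), p)
  m[ri, ci, drop = FALSE]
}

# mirror an arbitrary integer index into 1..n (whole-sample symmetric
# reflection, repeated as needed for pads wider than the image)
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  m <- (i - 1L) %% period
  m <- ifelse(m >= n, period - m, m)
  m + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
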