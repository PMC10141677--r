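#' Haar wavelet energy features
#'
#' Orthonormal 2-D Haar transform over 4 dyadic scales. The region is
#' first cropped (top-left) to the largest height/width divisible by 16 so
#' all four scales divide evenly, avoiding padding artifacts. At each
#' scale the current approximation is split into LL (approximation), LH
#' (detail along columns), HL (detail along rows) and HH (diagonal
#' detail); the feature is the mean squared coefficient (energy) of each
#' subband, and the next scale recurses on LL. Because the transform is
#' orthonormal, the size-weighted detail energies plus the final LL
#' energy reproduce the total signal energy exactly.
#'
#' @param pixels numeric matrix, at least 16x16.
#' @param n_scales number of dyadic scales (4 in this pipeline).
#' @return named numeric vector `s<scale>_<subband>`, 4 x `n_scales`
#'   values.
#' @export
haar_features <- function(pixels, n_scales = 4L) {
  blk <- 2^n_scales
  nr <- blk * (nrow(pixels) %/% blk)
  nc <- blk * (ncol(pixels) %/% blk)
  if (nr < blk || nc < blk) {
    stop("insufficient extent: Haar needs >= ", blk, "x", blk)
  }
  cur <- pixels[seq_len(nr), seq_len(nc), drop = FALSE]
  out <- numeric(0)
  for (s in seq_len(n_scales)) {
    odd_r <- seq(1, nrow(cur), by = 2); odd_c <- seq(1, ncol(cur), by = 2)
    a <- cur[odd_r, odd_c, drop = FALSE]       # (2i-1, 2j-1)
    b <- cur[odd_r, odd_c + 1, drop = FALSE]   # (2i-1, 2j)
    cc <- cur[odd_r + 1, odd_c, drop = FALSE]  # (2i,   2j-1)
    d <- cur[odd_r + 1, odd_c + 1, drop = FALSE]
    ll <- (a + b + cc + d) / 2
    lh <- (a - b + cc - d) / 2                 # column (horizontal) detail
    hl <- (a + b - cc - d) / 2                 # row (vertical) detail
    hh <- (a - b - cc + d) / 2
    e <- c(ll = mean(ll^2), lh = mean(lh^2), hl = mean(hl^2), hh = mean(hh^2))
    names(e) <- paste0("s", s, "_", names(e))
    out <- c(out, e)
    cur <- ll
  }
  out
}

#' Gabor filter kernel
#'
#' Complex Gabor kernel with an isotropic Gaussian envelope (sigma =
#' `size`/2, support half-width = `size`) and a plane-wave carrier of
#' wavelength lambda = `size` along the given orientation. The real
#' (even) part is DC-corrected so a constant image yields zero response.
#'
#' @param size envelope size s (also the carrier wavelength), pixels.
#' @param direction carrier direction in degrees (0 = along columns).
#' @return complex matrix of size `(2s+1) x (2s+1)`.
#' @keywords internal
gabor_kernel <- function(size, direction) {
  h <- as.integer(size)
  sigma <- size / 2
  lambda <- size
  th <- direction * pi / 180
  y <- matrix(seq(-h, h), 2 * h + 1, 2 * h + 1)          # row offset
  x <- t(y)                                              # col offset
  env <- exp(-(x^2 + y^2) / (2 * sigma^2))
  phase <- 2 * pi * (x * cos(th) + y * sin(th)) / lambda
  re <- env * cos(phase)
  re <- re - env * sum(re) / sum(env)                    # zero DC
  im <- env * sin(phase)
  # unit-L1 envelope: response amplitudes comparable across envelope sizes
  matrix(complex(real = re, imaginary = im) / sum(env), 2 * h + 1, 2 * h + 1)
}

#' Gabor bank features
#'
#' Mean response magnitude of the region under a bank of Gabor filters:
#' four orientations (matching the co-occurrence directions) times six
#' envelope sizes. The region is reflection-padded, filtered by FFT
#' convolution with the complex kernel, and each feature is the mean
#' magnitude of the response over the region.
#'
#' @param pixels numeric matrix, at least as large as the largest
#'   envelope size in each dimension.
#' @param directions orientation angles in degrees.
#' @param sizes envelope sizes in pixels.
#' @return named numeric vector `a<angle>_s<size>`,
#'   `length(directions) * length(sizes)` values.
#' @export
gabor_features <- function(pixels, directions = c(0, 45, 90, 135),
                           sizes = c(4, 6, 8, 12, 16, 24)) {
  if (min(nrow(pixels), ncol(pixels)) < max(sizes)) {
    stop("insufficient extent: region smaller than the largest envelope (",
         max(sizes), ")")
  }
  out <- numeric(0)
  for (s in sizes) {
    for (a in directions) {
      k <- gabor_kernel(s, a)
      resp <- complex(
        real = as.vector(conv2_same(pixels, Re(k))),
        imaginary = as.vector(conv2_same(pixels, Im(k))))
      v <- mean(Mod(resp))
      names(v) <- sprintf("a%d_s%d", as.integer(a), as.integer(s))
      out <- c(out, v)
    }
  }
  out
}
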