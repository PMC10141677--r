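#' Gray-level quantization for matrix-based features
#'
#' Uniform re-binning of the gray range \[0, L\] into `levels` bins:
#' `floor(I * levels / (L + 1))`, giving quantized values in
#' `0 .. levels - 1`. Both the co-occurrence and run-length features work
#' on this quantized grid (64 levels by default, which bounds the
#' co-occurrence matrix at 64x64 regardless of bit depth).
#'
#' @param pixels integer matrix with values in \[0, L\].
#' @param L gray-range maximum of the input.
#' @param levels number of quantized levels G.
#' @return integer matrix with values in `0 .. levels - 1`.
#' @export
quantize_gray <- function(pixels, L, levels) {
  q <- floor(pixels * (levels / (L + 1)))
  q[q > levels - 1] <- levels - 1
  q[q < 0] <- 0
  storage.mode(q) <- "integer"
  q
}

# (row, col) offset of one step along each of the four directions
direction_offset <- function(direction, d = 1L) {
  switch(as.character(direction),
    "0"   = c(0L, d),
    "45"  = c(d, d),
    "90"  = c(d, 0L),
    "135" = c(d, -d),
    stop("unknown direction: ", direction))
}

#' Gray-level co-occurrence matrix
#'
#' Joint distribution of quantized gray-level pairs at a fixed offset
#' (direction in \{0, 45, 90, 135\} degrees, distance `d` in pixels).
#' The matrix is symmetrized (each ordered pair counted in both
#' directions) and normalized to sum to 1.
#'
#' @param q integer matrix of quantized levels `0 .. levels - 1` (see
#'   [quantize_gray()]).
#' @param direction one of 0, 45, 90, 135 (degrees).
#' @param d inter-pixel distance, 1..5 in this pipeline.
#' @param levels number of gray levels G.
#' @return G x G matrix of pair probabilities.
#' @export
glcm <- function(q, direction, d, levels) {
  off <- direction_offset(direction, as.integer(d))
  dr <- off[1]; dc <- off[2]
  nr <- nrow(q); nc <- ncol(q)
  if (nr - dr < 1 || nc - abs(dc) < 1) {
    stop("insufficient extent: region smaller than offset (", dr, ",", dc, ")")
  }
  rows <- seq_len(nr - dr)                      # dr >= 0 always
  cols <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
  a <- q[rows, cols, drop = FALSE]
  b <- q[rows + dr, cols + dc, drop = FALSE]
  counts <- tabulate(as.vector(a) * levels + as.vector(b) + 1L,
                     nbins = levels * levels)
  C <- matrix(counts, levels, levels, byrow = TRUE)
  C <- C + t(C)
  C / sum(C)
}

#' Haralick-type statistics of a co-occurrence matrix
#'
#' The eleven classical second-order statistics: angular second moment,
#' contrast, correlation, sum of squares (variance), inverse difference
#' moment, sum average, sum variance, sum entropy, entropy, difference
#' variance, and difference entropy. Entropies use the natural logarithm
#' with the convention `0 * log 0 = 0`; correlation of a degenerate
#' (zero-variance) matrix is defined as 0. Gray-level indices are 1-based.
#'
#' @param P co-occurrence probability matrix from [glcm()].
#' @return named numeric vector of 11 statistics.
#' @export
glcm_features <- function(P) {
  G <- nrow(P)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  px <- rowSums(P)
  mu_x <- sum(seq_len(G) * px)
  var_x <- sum((seq_len(G) - mu_x)^2 * px)
  # sum and difference distributions p_{x+y}, p_{x-y}
  psum <- tapply(as.vector(P), as.vector(i + j), sum)          # k = 2..2G
  pdiff <- tapply(as.vector(P), as.vector(abs(i - j)), sum)    # k = 0..G-1
  ks <- as.numeric(names(psum))
  kd <- as.numeric(names(pdiff))
  ent <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  sum_avg <- sum(ks * psum)
  diff_avg <- sum(kd * pdiff)
  corr <- if (var_x > 0) (sum(i * j * P) - mu_x^2) / var_x else 0
  c(
    asm          = sum(P^2),
    contrast     = sum((i - j)^2 * P),
    correlation  = corr,
    sumofsqs     = sum((i - mu_x)^2 * P),
    idm          = sum(P / (1 + (i - j)^2)),
    sumaverage   = sum_avg,
    sumvariance  = sum((ks - sum_avg)^2 * psum),
    sumentropy   = ent(psum),
    entropy      = ent(P),
    diffvariance = sum((kd - diff_avg)^2 * pdiff),
    diffentropy  = ent(pdiff)
  )
}
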