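#' Plus/minus three sigma intensity normalization
#'
#' Standard preprocessing for MR texture analysis: the region's mean
#' illuminance \eqn{\mu} and population standard deviation \eqn{\sigma}
#' define `min_norm` \eqn{= \mu - 3\sigma} and `max_norm`
#' \eqn{= \mu + 3\sigma}; each pixel is remapped linearly so that
#' `min_norm` lands at 0 and `max_norm` at the gray-range maximum
#' \eqn{L = 2^{bit\_depth} - 1}, then clamped into \eqn{[0, L]} and
#' rounded (half away from zero):
#' \deqn{N(x,y) = L \cdot \frac{I(x,y) - (\mu - 3\sigma)}{6\sigma}}
#' For a near-Gaussian histogram this discards only the extreme tails
#' while standardizing location and scale across scans. A constant region
#' (\eqn{\sigma = 0}) maps to the constant \eqn{L/2} (rounded) rather than
#' dividing by zero.
#'
#' @param region a [region()] object, or an integer matrix (then
#'   `bit_depth` must be given).
#' @param bit_depth used when `region` is a plain matrix; also lets the
#'   clamp ceiling be forced to 255 on 12-bit input if desired.
#' @param ceiling_override optional clamp ceiling L replacing
#'   `2^bit_depth - 1` (e.g. 255 to compress 12-bit data onto the 8-bit
#'   range).
#' @return an object of class `normalized_region`: integer `pixels` in
#'   \[0, L\], plus `mu`, `sigma`, `min_norm`, `max_norm`, `L`.
#' @export
normalize_3sigma <- function(region, bit_depth = NULL, ceiling_override = NULL) {
  if (inherits(region, "region")) {
    pixels <- region$pixels
    bit_depth <- bit_depth %||% region$bit_depth
  } else {
    pixels <- region
    if (is.null(bit_depth)) stop("bit_depth required for a plain matrix")
  }
  stopifnot(is.matrix(pixels), length(pixels) > 0)
  L <- ceiling_override %||% (2^bit_depth - 1)
  mu <- mean(pixels)
  sigma <- sqrt(mean((pixels - mu)^2))  # population sd
  min_norm <- mu - 3 * sigma
  max_norm <- mu + 3 * sigma
  if (sigma > 0) {
    N <- L * (pixels - min_norm) / (max_norm - min_norm)
    out <- round_half_away(pmin(pmax(N, 0), L))
  } else {
    out <- matrix(round_half_away(L / 2), nrow(pixels), ncol(pixels))
  }
  structure(
    list(pixels = out, L = L, mu = mu, sigma = sigma,
         min_norm = min_norm, max_norm = max_norm),
    class = "normalized_region"
  )
}
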