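#' Run-length matrix of a quantized region
#'
#' Counts maximal runs of equal quantized gray level along one of the four
#' directions. Lines are the rows (0 degrees), columns (90), diagonals
#' (45) or anti-diagonals (135) of the grid; every pixel belongs to
#' exactly one line per direction, so the run-length-weighted pixel count
#' always equals the region's pixel count.
#'
#' @param q integer matrix of quantized levels (see [quantize_gray()]).
#' @param direction one of 0, 45, 90, 135 (degrees).
#' @param levels number of gray levels G.
#' @return G x max_run_length integer count matrix (rows: gray level
#'   `0 .. G-1`; columns: run length).
#' @export
run_length_matrix <- function(q, direction, levels) {
  lines <- switch(as.character(direction),
    "0"   = split(q, row(q)),
    "90"  = split(q, col(q)),
    "45"  = split(q, row(q) - col(q)),
    "135" = split(q, row(q) + col(q)),
    stop("unknown direction: ", direction))
  max_len <- max(nrow(q), ncol(q))
  M <- matrix(0L, nrow = levels, ncol = max_len)
  for (ln in lines) {
    r <- rle(as.vector(ln))
    for (k in seq_along(r$lengths)) {
      g <- r$values[k] + 1L
      l <- r$lengths[k]
      M[g, l] <- M[g, l] + 1L
    }
  }
  M
}

#' Run-length (Galloway) statistics
#'
#' Five statistics of the run-length matrix: short-run emphasis, long-run
#' emphasis, gray-level nonuniformity, run-length nonuniformity, and run
#' percentage (number of runs / number of pixels).
#'
#' @param M run-length count matrix from [run_length_matrix()].
#' @param n_pixels number of pixels in the region (denominator of run
#'   percentage).
#' @return named numeric vector of 5 statistics.
#' @export
rlm_stats <- function(M, n_pixels) {
  n_runs <- sum(M)
  lens <- seq_len(ncol(M))
  runs_by_len <- colSums(M)
  runs_by_gray <- rowSums(M)
  c(
    sre = sum(runs_by_len / lens^2) / n_runs,
    lre = sum(runs_by_len * lens^2) / n_runs,
    gln = sum(runs_by_gray^2) / n_runs,
    rln = sum(runs_by_len^2) / n_runs,
    rp  = n_runs / n_pixels
  )
}

#' Run-length features of a region for one direction
#'
#' @param q quantized integer matrix.
#' @param direction one of 0, 45, 90, 135.
#' @param levels number of gray levels G.
#' @return named numeric vector of 5 statistics.
#' @export
rlm_features <- function(q, direction, levels) {
  M <- run_length_matrix(q, direction, levels)
  rlm_stats(M, length(q))
}
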