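# Independent brute-force oracles for the matrix-based texture features,
# written against the definitions (pair/run enumeration), not the package
# implementation.

# co-occurrence by explicit pair enumeration
bf_glcm <- function(q, direction, d, levels) {
  off <- switch(as.character(direction),
                "0" = c(0, d), "45" = c(d, d), "90" = c(d, 0),
                "135" = c(d, -d))
  counts <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        i <- q[r, cc] + 1; j <- q[r2, c2] + 1
        counts[i, j] <- counts[i, j] + 1
        counts[j, i] <- counts[j, i] + 1
      }
    }
  }
  counts / sum(counts)
}

# Haralick statistics straight from the definition formulas
bf_glcm_stats <- function(P) {
  G <- nrow(P)
  asm <- 0; contrast <- 0; idm <- 0; ent <- 0; ssq <- 0
  px <- rowSums(P)
  mu <- sum(seq_len(G) * px)
  sigma2 <- sum((seq_len(G) - mu)^2 * px)
  psum <- numeric(2 * G); pdiff <- numeric(G)
  cross <- 0
  for (i in seq_len(G)) for (j in seq_len(G)) {
    p <- P[i, j]
    asm <- asm + p^2
    contrast <- contrast + (i - j)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    ssq <- ssq + (i - mu)^2 * p
    cross <- cross + i * j * p
    if (p > 0) ent <- ent - p * log(p)
    psum[i + j] <- psum[i + j] + p
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p
  }
  sa <- sum(seq_along(psum) * psum)
  sv <- sum((seq_along(psum) - sa)^2 * psum)
  se <- -sum(psum[psum > 0] * log(psum[psum > 0]))
  kd <- seq_along(pdiff) - 1
  dav <- sum(kd * pdiff)
  dv <- sum((kd - dav)^2 * pdiff)
  de <- -sum(pdiff[pdiff > 0] * log(pdiff[pdiff > 0]))
  corr <- if (sigma2 > 0) (cross - mu^2) / sigma2 else 0
  c(asm = asm, contrast = contrast, correlation = corr, sumofsqs = ssq,
    idm = idm, sumaverage = sa, sumvariance = sv, sumentropy = se,
    entropy = ent, diffvariance = dv, diffentropy = de)
}

# run-length matrix by explicit line walking
bf_rlm <- function(q, direction, levels) {
  nr <- nrow(q); nc <- ncol(q)
  step <- switch(as.character(direction),
                 "0" = c(0, 1), "90" = c(1, 0), "45" = c(1, 1),
                 "135" = c(1, -1))
  starts <- switch(as.character(direction),
    "0"   = lapply(seq_len(nr), function(r) c(r, 1)),
    "90"  = lapply(seq_len(nc), function(cc) c(1, cc)),
    "45"  = c(lapply(seq_len(nc), function(cc) c(1, cc)),
              lapply(seq_len(nr)[-1], function(r) c(r, 1))),
    "135" = c(lapply(seq_len(nc), function(cc) c(1, cc)),
              lapply(seq_len(nr)[-1], function(r) c(r, nc))))
  M <- matrix(0, levels, max(nr, nc))
  for (s in starts) {
    vals <- c()
    r <- s[1]; cc <- s[2]
    while (r >= 1 && r <= nr && cc >= 1 && cc <= nc) {
      vals <- c(vals, q[r, cc])
      r <- r + step[1]; cc <- cc + step[2]
    }
    run_val <- vals[1]; run_len <- 1
    for (v in vals[-1]) {
      if (v == run_val) run_len <- run_len + 1
      else {
        M[run_val + 1, run_len] <- M[run_val + 1, run_len] + 1
        run_val <- v; run_len <- 1
      }
    }
    M[run_val + 1, run_len] <- M[run_val + 1, run_len] + 1
  }
  M
}

bf_rlm_stats <- function(M, n_pixels) {
  n_runs <- sum(M)
  sre <- 0; lre <- 0; rln <- 0
  for (l in seq_len(ncol(M))) {
    rl <- sum(M[, l])
    sre <- sre + rl / l^2
    lre <- lre + rl * l^2
    rln <- rln + rl^2
  }
  gln <- sum(rowSums(M)^2)
  c(sre = sre / n_runs, lre = lre / n_runs, gln = gln / n_runs,
    rln = rln / n_runs, rp = n_runs / n_pixels)
}

# direct evaluation of the normalization equations, as printed: the
# window bounds min_norm / max_norm are the defined quantities
bf_normalize <- function(pixels, L) {
  mu <- mean(pixels)
  sigma <- sqrt(mean((pixels - mu)^2))
  if (sigma == 0) return(matrix(round(L / 2), nrow(pixels), ncol(pixels)))
  min_norm <- mu - 3 * sigma
  max_norm <- mu + 3 * sigma
  N <- L * (pixels - min_norm) / (max_norm - min_norm)
  out <- ifelse(N > L, L, ifelse(N < 0, 0, N))
  sign(out) * floor(abs(out) + 0.5)
}

# small random test regions
random_grid <- function(nr, nc, levels) {
  matrix(sample(0L:(levels - 1L), nr * nc, replace = TRUE), nr, nc)
}

# a region object around a plain matrix
as_region <- function(pixels, bit_depth = 8L, ...) {
  structure(c(list(pixels = pixels, bit_depth = bit_depth), list(...)),
            class = "region")
}

# small, fast synthetic cohort spec for tests
test_cohort_spec <- function(seed = 1L, n_patients = 6L, n_images = 8L, ...) {
  cohort_spec(n_patients = n_patients, n_images = n_images, seed = seed, ...)
}
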