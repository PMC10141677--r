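test_that("Haar energies localize stripes and conserve energy", {
  # constant region: all detail energies 0, scale-1 LL energy = (2c/..)^2
  hc <- haar_features(matrix(6, 16, 16))
  detail <- grep("_(lh|hl|hh)$", names(hc))
  expect_true(all(hc[detail] == 0))
  expect_equal(hc[["s1_ll"]], (6 * 2)^2)  # orthonormal 2-D step doubles a constant

  # alternating rows (period 2): all detail energy in the scale-1
  # row-detail subband
  st <- matrix(rep(c(0, 100), 16), 32, 32)
  hs <- haar_features(st)
  expect_gt(hs[["s1_hl"]], 0)
  expect_equal(hs[["s1_lh"]], 0)
  expect_equal(hs[["s1_hh"]], 0)
  expect_true(all(hs[grep("^s[234]_(lh|hl|hh)$", names(hs))] == 0))

  # Parseval: size-weighted detail energies + final LL = total energy
  set.seed(31)
  m <- matrix(rnorm(32 * 32), 32, 32)
  h <- haar_features(m)
  sizes <- c(s1 = 256, s2 = 64, s3 = 16, s4 = 4)
  acc <- h[["s4_ll"]] * sizes[["s4"]]
  for (s in names(sizes)) {
    acc <- acc + sum(h[paste0(s, "_", c("lh", "hl", "hh"))]) * sizes[[s]]
  }
  expect_equal(acc, sum(m^2), tolerance = 1e-10)

  # non-dyadic sizes are cropped to the largest multiple of 16
  expect_equal(haar_features(m[1:20, 1:19]), haar_features(m[1:16, 1:16]))
  expect_error(haar_features(matrix(0, 8, 8)), "insufficient extent")
})

test_that("Gabor bank is DC-free, scale- and orientation-selective", {
  cv <- gabor_features(matrix(100, 32, 32))
  expect_lt(max(abs(cv)), 1e-9)

  # grating of wavelength 8 along columns: matched filter (0 deg, s=8) wins
  g <- 128 + 100 * sin(2 * pi * outer(rep(1, 48), 1:48) / 8)
  gv <- gabor_features(g)
  expect_equal(names(which.max(gv)), "a0_s8")
  expect_true(all(gv[["a0_s8"]] > gv[names(gv) != "a0_s8"]))

  # rotating the region by 90 degrees permutes the orientation index
  set.seed(32)
  r <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
  rot <- t(r)[32:1, ]
  a <- gabor_features(r)
  b <- gabor_features(rot)
  for (s in c(4, 6, 8, 12, 16, 24)) {
    expect_equal(b[[sprintf("a90_s%d", s)]], a[[sprintf("a0_s%d", s)]],
                 tolerance = 1e-6)
  }

  expect_error(gabor_features(matrix(0, 16, 16)), "insufficient extent")
})
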