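# The spectral branch primitives: grid re-layout, transform pair, SE
# gating.  Oracles: stats::fft for the transform, dense summation for
# Parseval, explicit enumeration for the 2x2 layout.

test_that("patch-grid re-layout is a row-major bijection", {
  set.seed(1)
  tok <- matrix(rnorm(196 * 8), 196, 8)
  grid <- to_patch_grid(tok, c(14, 14))
  expect_identical(from_patch_grid(grid), tok)   # bitwise round trip
  # token k sits at cell (k %/% Wp, k %% Wp) (0-based row-major)
  for (k in c(1L, 14L, 15L, 100L, 196L)) {
    y <- (k - 1L) %/% 14L + 1L; x <- (k - 1L) %% 14L + 1L
    expect_identical(grid[, y, x], tok[k, ])
  }
  expect_error(to_patch_grid(tok, c(13, 14)), "does not match")
})

test_that("2x2 grid layout distinguishes arrangement from its transpose", {
  tok <- matrix(as.numeric(1:8), 4, 2)       # four distinct rows
  g <- to_patch_grid(tok, c(2, 2))
  # row-major: token 2 -> cell (1,2), token 3 -> cell (2,1)
  expect_identical(g[, 1, 2], tok[2, ])
  expect_identical(g[, 2, 1], tok[3, ])
  gt <- aperm(g, c(1, 3, 2))                 # transposed layout
  expect_false(identical(from_patch_grid(gt), tok))
})

test_that("transform pair satisfies the unnormalised-forward contract", {
  set.seed(2)
  grid <- array(rnorm(5 * 8 * 8), c(5, 8, 8))
  sp <- fft2(grid)
  # oracle: stats::fft channel by channel
  for (c in 1:5)
    expect_rel_equal(sp[c, , ], stats::fft(grid[c, , ]), 1e-10)
  back <- ifft2(sp)
  expect_lt(max(abs(back - grid)), 1e-5)
  # constant grid: only the DC coefficient, value c * Hp * Wp
  cg <- array(0.7, c(2, 4, 4))
  spc <- fft2(cg)
  expect_equal(Re(spc[1, 1, 1]), 0.7 * 16, tolerance = 1e-10)
  expect_lt(max(Mod(spc[, -1, ]), Mod(spc[, , -1])), 1e-10)
})

test_that("Parseval equality holds against a dense-transform oracle", {
  set.seed(3)
  x <- matrix(rnorm(16), 4, 4)
  # dense DFT oracle, explicit double loop over frequencies
  dense <- matrix(0 + 0i, 4, 4)
  for (k1 in 0:3) for (k2 in 0:3) {
    s <- 0 + 0i
    for (n1 in 0:3) for (n2 in 0:3)
      s <- s + x[n1 + 1, n2 + 1] * exp(-2i * pi * (k1 * n1 + k2 * n2) / 4)
    dense[k1 + 1, k2 + 1] <- s
  }
  sp <- fft2(array(x, c(1, 4, 4)))
  expect_rel_equal(sp[1, , ], dense, 1e-10)
  expect_equal(sum(x^2), sum(Mod(dense)^2) / 16, tolerance = 1e-10)
})

test_that("ifft2 rejects a corrupted (asymmetric) spectrum", {
  sp <- fft2(array(rnorm(16), c(1, 4, 4)))
  sp[1, 2, 2] <- sp[1, 2, 2] + 10i           # break conjugate symmetry
  expect_error(ifft2(sp), "imaginary residue")
})

test_that("SE gate: bounds, zero-weight value, descriptor invariances", {
  D <- 6L
  set.seed(4)
  grid <- array(rnorm(D * 4 * 4), c(D, 4, 4))
  sp <- fft2(grid)
  zero <- list(W1 = matrix(0, D, 2), b1 = numeric(2),
               W2 = matrix(0, 2, D), b2 = numeric(D))
  expect_equal(se_gate(sp, zero), rep(0.5, D))
  p <- list(W1 = matrix(rnorm(D * 2, sd = 0.5), D), b1 = rnorm(2),
            W2 = matrix(rnorm(2 * D, sd = 0.5), 2), b2 = rnorm(D))
  g <- se_gate(sp, p)
  expect_true(all(g > 0 & g < 1))
  # translation invariance: rolling the grid changes phase only
  rolled <- grid[, c(3:4, 1:2), c(2:4, 1)]
  d1 <- rowMeans(matrix(Mod(fft2(grid)), D))
  d2 <- rowMeans(matrix(Mod(fft2(rolled)), D))
  expect_lt(max(abs(d1 - d2)), 1e-5 * max(abs(d1)))
  # absolute homogeneity: doubling the grid doubles the descriptor
  d3 <- rowMeans(matrix(Mod(fft2(2 * grid)), D))
  expect_rel_equal(d3, 2 * d1, 1e-10)
})

test_that("channel gating commutes with the inverse transform", {
  set.seed(5)
  D <- 4L
  grid <- array(rnorm(D * 6 * 6), c(D, 6, 6))
  gate <- stats::runif(D, 0.1, 0.9)
  sp <- fft2(grid)
  path1 <- ifft2(apply_gate(sp, gate))       # gate in frequency domain
  path2 <- grid * gate                       # scale in spatial domain
  expect_lt(max(abs(path1 - path2)), 1e-5)
  expect_identical(apply_gate(sp, rep(1, D)), sp)
  expect_lt(max(abs(ifft2(apply_gate(sp, rep(0, D))))), 1e-12)
  expect_error(apply_gate(sp, rep(1, D + 1)), "gate length")
})

test_that("gated spectra of real grids invert to real grids", {
  set.seed(6)
  for (rep_i in 1:5) {
    grid <- array(rnorm(3 * 8 * 8), c(3, 8, 8))
    gate <- stats::runif(3)
    expect_silent(ifft2(apply_gate(fft2(grid), gate)))
  }
})
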