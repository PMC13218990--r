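# Handcrafted descriptor families.

test_that("constant images give degenerate histograms and GLCM", {
  img <- array(0.5, c(3, 32, 32))
  ch <- extract_descriptor(img, descriptor_spec("color_histogram"),
                           resize_to = NULL)
  expect_length(ch, 96L)
  expect_equal(sum(ch), 3)                    # per-channel density sums
  expect_equal(sum(ch > 0), 3L)               # one occupied bin per channel
  gl <- extract_descriptor(img, descriptor_spec("glcm"), resize_to = NULL)
  expect_equal(unname(gl[c("energy", "contrast")]), c(1, 0))
  lh <- extract_descriptor(img, descriptor_spec("luminance_histogram"),
                           resize_to = NULL)
  expect_equal(sum(lh), 1)
  expect_equal(sum(lh > 0), 1L)
})

test_that("LBP of a period-2 checkerboard matches brute-force enumeration", {
  S <- 8L
  g <- outer(1:S, 1:S, function(i, j) (i + j) %% 2)
  img <- aperm(array(g, c(S, S, 3)), c(3, 1, 2))
  got <- extract_descriptor(img, descriptor_spec("lbp"), resize_to = NULL)
  # oracle: per-pixel 3x3 comparison, bit order E,SE,S,SW,W,NW,N,NE
  shifts <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
                 c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  codes <- c()
  for (y in 2:(S - 1)) for (x in 2:(S - 1)) {
    code <- 0L
    for (b in seq_along(shifts))
      code <- code + as.integer(g[y + shifts[[b]][1], x + shifts[[b]][2]] >=
                                  g[y, x]) * 2L^(b - 1L)
    codes <- c(codes, code)
  }
  uniform_bin <- function(cd) {
    bits <- as.integer(intToBits(cd)[1:8])
    if (sum(bits != bits[c(2:8, 1)]) <= 2L) sum(bits) + 1L else 10L
  }
  oracle <- tabulate(vapply(codes, uniform_bin, 1L), 10L) / length(codes)
  expect_equal(got, oracle, tolerance = 1e-12)
  # alternating pattern: mass sits on exactly two bins (all-0s / all-1s)
  expect_equal(sum(got > 0), 2L)
})

test_that("histogram families are permutation invariant; texture families are not", {
  img <- rand_images(1, 32, seed = 41)[, , , 1]
  perm <- withr::with_seed(42, sample(32 * 32))
  shuffled <- img
  for (c in 1:3) {
    m <- img[c, , ]
    shuffled[c, , ] <- matrix(m[perm], 32, 32)
  }
  for (fam in c("color_histogram", "luminance_histogram")) {
    sp <- descriptor_spec(fam)
    expect_equal(extract_descriptor(img, sp, resize_to = NULL),
                 extract_descriptor(shuffled, sp, resize_to = NULL),
                 tolerance = 1e-12)
  }
  for (fam in c("hog", "lbp", "glcm")) {
    sp <- descriptor_spec(fam)
    a <- extract_descriptor(img, sp, resize_to = NULL)
    b <- extract_descriptor(shuffled, sp, resize_to = NULL)
    expect_gt(max(abs(a - b)), 1e-6)
  }
})

test_that("descriptor lengths match the documented formulae", {
  img <- rand_images(1, 64, seed = 43)[, , , 1]
  for (fam in c("color_histogram", "luminance_histogram", "hog",
                "lbp", "glcm")) {
    sp <- descriptor_spec(fam)
    v <- extract_descriptor(img, sp, resize_to = 64L)
    expect_length(v, descriptor_length(sp, image_size = 64L))
    expect_true(all(is.finite(v)))
    # deterministic
    expect_identical(v, extract_descriptor(img, sp, resize_to = 64L))
  }
  # at the protocol resolution HOG has (224/8 - 1)^2 * 36 dims
  expect_equal(descriptor_length(descriptor_spec("hog")), 27L^2 * 36L)
  expect_error(extract_descriptor(matrix(0, 4, 4),
                                  descriptor_spec("glcm")), "RGB")
})
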