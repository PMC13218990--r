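## Five handcrafted texture descriptor families used as comparison
## baselines: colour histogram, luminance histogram, HOG, LBP, GLCM.
## Implemented from first principles (no imaging package assumed); the
## operator parameters are fixed, documented defaults.

#' Describe a handcrafted feature family
#'
#' @param family one of `"color_histogram"`, `"luminance_histogram"`,
#'   `"hog"`, `"lbp"`, `"glcm"`.
#' @param ... family-specific parameters overriding the defaults:
#'   `bins` (32/channel for colour, 64 for luminance), `cell_size` and
#'   `orientations` for HOG (8 px, 9 bins), `levels` for GLCM (32).
#' @return an object of class `fga_descriptor_spec`.
#' @export
descriptor_spec <- function(family = c("color_histogram",
                                       "luminance_histogram", "hog",
                                       "lbp", "glcm"), ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    color_histogram = list(bins = 32L),
    luminance_histogram = list(bins = 64L),
    hog = list(orientations = 9L, cell_size = 8L, block_size = 2L),
    lbp = list(),
    glcm = list(levels = 32L))
  ov <- list(...)
  defaults[names(ov)] <- ov
  structure(c(list(family = family), defaults),
            class = "fga_descriptor_spec")
}

#' Length of the vector a descriptor spec produces
#'
#' @param spec an [descriptor_spec()].
#' @param image_size tile side after resizing (default 224).
#' @return integer vector length.
#' @export
descriptor_length <- function(spec, image_size = 224L) {
  switch(spec$family,
    color_histogram = 3L * spec$bins,
    luminance_histogram = spec$bins,
    hog = {
      nc <- image_size %/% spec$cell_size
      nb <- nc - spec$block_size + 1L
      nb * nb * spec$block_size^2 * spec$orientations
    },
    lbp = 10L,
    glcm = 5L)
}

#' Extract a handcrafted descriptor from an RGB image
#'
#' The image is bilinearly resized to `resize_to` x `resize_to`
#' (default 224, the protocol's working resolution) before extraction.
#' Family semantics:
#' \describe{
#'   \item{color_histogram}{32 bins per RGB channel, each channel's
#'     histogram normalised to sum 1 (96 dims; sums to 3).}
#'   \item{luminance_histogram}{64-bin histogram of
#'     Y = 0.299 R + 0.587 G + 0.114 B, normalised to sum 1.}
#'   \item{hog}{gradient-orientation histograms: 9 unsigned orientation
#'     bins with linear interpolation, 8 x 8-pixel cells, 2 x 2-cell
#'     blocks, L2 block normalisation, on the luminance channel.}
#'   \item{lbp}{uniform local binary patterns from the 3 x 3
#'     neighbourhood (8 neighbours, radius 1): 9 uniform bins (by
#'     number of set bits) plus one non-uniform bin, normalised (10
#'     dims).}
#'   \item{glcm}{grey co-occurrence at 32 levels, distance 1, angles
#'     0/45/90/135 degrees, symmetric and normalised; the statistics
#'     contrast, correlation, energy (angular second moment),
#'     homogeneity and dissimilarity averaged over angles (5 dims).}
#' }
#'
#' @param image numeric array 3 x S x S in \[0, 1\].
#' @param spec an [descriptor_spec()].
#' @param resize_to working resolution (`NULL` keeps the input size).
#' @return numeric feature vector (finite, fixed length per family).
#' @export
extract_descriptor <- function(image, spec, resize_to = 224L) {
  stopifnot(inherits(spec, "fga_descriptor_spec"))
  d <- dim(image)
  if (length(d) != 3L || d[1L] != 3L)
    stopf("expected an RGB image as a 3 x S x S array")
  if (!is.null(resize_to) && d[2L] != resize_to)
    image <- bilinear_resize(image, resize_to, resize_to)
  switch(spec$family,
    color_histogram = desc_color_hist(image, spec$bins),
    luminance_histogram = desc_lum_hist(image, spec$bins),
    hog = desc_hog(luma(image), spec),
    lbp = desc_lbp(luma(image)),
    glcm = desc_glcm(luma(image), spec$levels))
}

hist01 <- function(v, bins) {
  idx <- pmin(pmax(floor(v * bins), 0), bins - 1L) + 1L
  tabulate(idx, bins) / length(v)
}

desc_color_hist <- function(img, bins) {
  as.vector(sapply(1:3, function(c) hist01(img[c, , ], bins)))
}

desc_lum_hist <- function(img, bins) hist01(luma(img), bins)

desc_hog <- function(g, spec) {
  S <- nrow(g)
  cs <- spec$cell_size; nb <- spec$orientations; bs <- spec$block_size
  ncell <- S %/% cs
  # centred gradients with replicated borders
  gx <- (g[, c(2:S, S)] - g[, c(1, 1:(S - 1))]) / 2
  gy <- (g[c(2:S, S), ] - g[c(1, 1:(S - 1)), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- (atan2(gy, gx) / pi * 180) %% 180          # unsigned, [0, 180)
  # linear interpolation between the two nearest orientation bins
  bw <- 180 / nb
  pos <- ang / bw - 0.5
  b0 <- floor(pos)
  w1 <- pos - b0
  b0 <- b0 %% nb; b1 <- (b0 + 1L) %% nb
  cell_y <- pmin((row(g) - 1L) %/% cs, ncell - 1L)
  cell_x <- pmin((col(g) - 1L) %/% cs, ncell - 1L)
  cellid <- cell_y * ncell + cell_x
  acc <- function(bin, w) {
    key <- cellid * nb + bin + 1L
    v <- rowsum(as.vector(mag * w), as.vector(key))
    out <- numeric(ncell * ncell * nb)
    out[as.integer(rownames(v))] <- v
    out
  }
  hist <- acc(b0, 1 - w1) + acc(b1, w1)
  H <- array(hist, c(nb, ncell, ncell))             # [bin, cx, cy]
  nblk <- ncell - bs + 1L
  out <- numeric(nblk * nblk * bs * bs * nb)
  k <- 1L
  for (by in seq_len(nblk)) for (bx in seq_len(nblk)) {
    v <- as.vector(H[, bx:(bx + bs - 1L), by:(by + bs - 1L)])
    v <- v / sqrt(sum(v^2) + 1e-12)
    out[k:(k + length(v) - 1L)] <- v
    k <- k + length(v)
  }
  out
}

## 3x3-neighbourhood LBP codes for the interior pixels; order of
## neighbour bits: E, SE, S, SW, W, NW, N, NE (bit 0 .. bit 7).
lbp_codes <- function(g) {
  S <- nrow(g)
  i <- 2:(S - 1)
  ctr <- g[i, i]
  shifts <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
                 c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  code <- matrix(0L, S - 2L, S - 2L)
  for (b in seq_along(shifts)) {
    sh <- shifts[[b]]
    nbv <- g[i + sh[1L], i + sh[2L]]
    code <- code + as.integer(nbv >= ctr) * 2L^(b - 1L)
  }
  code
}

## Uniform mapping: codes with <= 2 circular 0/1 transitions map to a
## bin indexed by their popcount (0..8); the rest share bin 10.
lbp_uniform_map <- function() {
  sapply(0:255, function(cd) {
    bits <- as.integer(intToBits(cd)[1:8])
    trans <- sum(bits != bits[c(2:8, 1)])
    if (trans <= 2L) sum(bits) + 1L else 10L
  })
}

desc_lbp <- function(g) {
  map <- lbp_uniform_map()
  binned <- map[lbp_codes(g) + 1L]
  tabulate(binned, 10L) / length(binned)
}

desc_glcm <- function(g, levels) {
  q <- pmin(pmax(floor(g * levels), 0), levels - 1L) + 1L
  S <- nrow(q)
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))  # 0,45,90,135 deg
  stats <- sapply(offsets, function(off) {
    dy <- off[1L]; dx <- off[2L]
    ys <- max(1, 1 - dy):min(S, S - dy)
    xs <- max(1, 1 - dx):min(S, S - dx)
    a <- q[ys, xs]
    b <- q[ys + dy, xs + dx]
    P <- matrix(0, levels, levels)
    v <- rowsum(rep(1, length(a)), as.vector((a - 1L) * levels + b))
    P[as.integer(rownames(v))] <- v
    P <- P + t(P)                       # symmetric
    P <- P / sum(P)
    ii <- row(P); jj <- col(P)
    mu_i <- sum(ii * P); mu_j <- sum(jj * P)
    sd_i <- sqrt(sum((ii - mu_i)^2 * P)); sd_j <- sqrt(sum((jj - mu_j)^2 * P))
    corr <- if (sd_i > 1e-12 && sd_j > 1e-12)
      sum((ii - mu_i) * (jj - mu_j) * P) / (sd_i * sd_j) else 1
    c(contrast = sum((ii - jj)^2 * P),
      correlation = corr,
      energy = sum(P^2),
      homogeneity = sum(P / (1 + (ii - jj)^2)),
      dissimilarity = sum(abs(ii - jj) * P))
  })
  rowMeans(stats)
}
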