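## Synthetic two-class H&E-like texture tiles.  The class signal is
## partly spectral by construction: the benign-like class uses a
## steeper power-law field (smoother, low-frequency texture, few round
## gland blobs), the malignant-like class a flatter spectrum plus
## stronger speckle and more irregular, eccentric blobs (high-frequency
## content).  Colour comes from Beer-Lambert mixing of two
## optical-density stain vectors (hematoxylin-like and eosin-like).

#' Specification of the synthetic H&E dataset
#'
#' Defaults define the reference fixture: 64 x 64 tiles, 200 images per
#' class, spectral slope beta 3.5 (benign) vs 1.5 (malignant), speckle
#' amplitude 0.04 vs 0.08, 3-6 rounder smooth blobs vs 4-8 more
#' eccentric rough blobs.  The class contrast is deliberately carried
#' mostly by the spectral slope (texture smoothness), with overlapping
#' blob counts, so purely spatial shortcuts are weak and a
#' frequency-aware encoder has measurable headroom over the spatial
#' baseline variants.  The generator refuses specs with
#' `beta[benign] <= beta[malignant]` (the smoothness ordering is the
#' stated class contrast) unless `override = TRUE`.
#'
#' @param image_size tile side in pixels (>= 16).
#' @param n_per_class images per class.
#' @param beta length-2 power-law slopes `c(benign, malignant)`.
#' @param blob_count list of length-2 integer ranges per class.
#' @param blob_eccentricity list of length-2 axis-ratio ranges.
#' @param speckle_amplitude per-class white-noise sd added to the
#'   nuclear map.
#' @param boundary_roughness per-class blob-contour perturbation scale.
#' @param stain_matrix 2 x 3 optical-density vectors (rows:
#'   hematoxylin-like, eosin-like; Ruifrok-Johnston-style constants).
#' @param seed RNG seed.
#' @param override allow a spec violating the beta ordering.
#' @return an object of class `fga_synth_spec`.
#' @export
synth_spec <- function(image_size = 64L, n_per_class = 200L,
                       beta = c(benign = 3.5, malignant = 1.5),
                       blob_count = list(benign = c(3L, 6L),
                                         malignant = c(4L, 8L)),
                       blob_eccentricity = list(benign = c(1, 2),
                                                malignant = c(1.5, 3)),
                       speckle_amplitude = c(benign = 0.04,
                                             malignant = 0.08),
                       boundary_roughness = c(benign = 0.05,
                                              malignant = 0.25),
                       stain_matrix = rbind(
                         hematoxylin = c(0.65, 0.70, 0.29),
                         eosin = c(0.07, 0.99, 0.11)),
                       seed = 1L, override = FALSE) {
  if (image_size < 16L) stopf("image_size must be >= 16")
  if (n_per_class < 1L) stopf("n_per_class must be >= 1")
  if (beta[1L] <= beta[2L] && !isTRUE(override))
    stopf(paste("benign beta (%.2f) must exceed malignant beta (%.2f):",
                "the benign class is the smoother texture by construction",
                "(set override = TRUE to force)"), beta[1L], beta[2L])
  structure(list(image_size = as.integer(image_size),
                 n_per_class = as.integer(n_per_class), beta = beta,
                 blob_count = blob_count,
                 blob_eccentricity = blob_eccentricity,
                 speckle_amplitude = speckle_amplitude,
                 boundary_roughness = boundary_roughness,
                 stain_matrix = stain_matrix, seed = as.integer(seed)),
            class = "fga_synth_spec")
}

#' Gaussian random field with a power-law spectrum
#'
#' White noise is shaped in the frequency domain with amplitude
#' proportional to |f|^(-beta/2) (the DC term zeroed), inverse
#' transformed and min-max normalised to \[0, 1\].  `beta = 0` gives
#' white noise; larger beta gives smoother, spatially correlated
#' fields.  Consumes the current RNG stream.
#'
#' @param size field side in pixels (>= 16).
#' @param beta nonnegative spectral slope.
#' @return numeric `size` x `size` matrix in \[0, 1\].
#' @export
spectral_field <- function(size, beta) {
  stopifnot(size >= 16, beta >= 0)
  noise <- matrix(stats::rnorm(size * size), size, size)
  fr <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
  kmag <- sqrt(outer(fr^2, fr^2, "+"))
  amp <- matrix(0, size, size)
  amp[kmag > 0] <- kmag[kmag > 0]^(-beta / 2)
  f <- Re(bdft2(bdft2(noise) * amp, inverse = TRUE))
  rng <- range(f)
  if (rng[2L] - rng[1L] < 1e-12) return(matrix(0.5, size, size))
  (f - rng[1L]) / (rng[2L] - rng[1L])
}

## Soft elliptical blob mask with a perturbed boundary, accumulated
## into the nuclear map.
stamp_blobs <- function(S, n_blobs, ecc_range, roughness) {
  yy <- matrix(seq_len(S), S, S)
  xx <- t(yy)
  m <- matrix(0, S, S)
  for (i in seq_len(n_blobs)) {
    cy <- stats::runif(1, 0.1 * S, 0.9 * S)
    cx <- stats::runif(1, 0.1 * S, 0.9 * S)
    r0 <- stats::runif(1, S / 10, S / 5)
    ecc <- stats::runif(1, ecc_range[1L], ecc_range[2L])
    th <- stats::runif(1, 0, pi)
    a1 <- stats::runif(1, -1, 1); a2 <- stats::runif(1, -1, 1)
    ps1 <- stats::runif(1, 0, 2 * pi); ps2 <- stats::runif(1, 0, 2 * pi)
    u <- (yy - cy) * cos(th) + (xx - cx) * sin(th)
    v <- -(yy - cy) * sin(th) + (xx - cx) * cos(th)
    rho <- sqrt((u / (r0 * sqrt(ecc)))^2 + (v / (r0 / sqrt(ecc)))^2)
    phi <- atan2(v, u)
    bnd <- 1 + roughness * (a1 * sin(2 * phi + ps1) + a2 * sin(3 * phi + ps2))
    bnd <- pmax(bnd, 0.3)
    m <- m + exp(-(rho / bnd)^4)
  }
  pmin(m, 1)
}

#' Generate a synthetic two-class H&E-like dataset
#'
#' For each image: a power-law base field with the class's beta (the
#' eosin/cytoplasm map); elliptical gland-like blobs stamped with
#' class-dependent count, eccentricity and boundary roughness (the
#' hematoxylin/nuclear map); class-specific white speckle; and
#' Beer-Lambert colourisation `RGB = exp(-OD)` through the stain
#' matrix.  Classes are exactly balanced (class 1 = benign-like,
#' class 2 = malignant-like) and the output is bitwise deterministic
#' under `spec$seed`.
#'
#' @param spec an [synth_spec()].
#' @return list with `images` (array 3 x S x S x n, values in
#'   \[0, 1\]), `labels` (integer 1/2) and `classes`
#'   (`c("benign", "malignant")`).
#' @export
generate_dataset <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "fga_synth_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  S <- spec$image_size
  n <- 2L * spec$n_per_class
  images <- array(0, c(3L, S, S, n))
  labels <- rep(1:2, each = spec$n_per_class)
  for (i in seq_len(n)) {
    cl <- labels[i]
    base <- spectral_field(S, spec$beta[cl])
    nb <- sample(spec$blob_count[[cl]][1L]:spec$blob_count[[cl]][2L], 1L)
    nucl <- stamp_blobs(S, nb, spec$blob_eccentricity[[cl]],
                        spec$boundary_roughness[cl])
    speck <- matrix(stats::rnorm(S * S, sd = spec$speckle_amplitude[cl]), S)
    h_conc <- pmin(pmax(0.25 + 0.85 * nucl + speck, 0), 1.3)
    e_conc <- 0.25 + 0.75 * base
    od <- outer(spec$stain_matrix["hematoxylin", ], h_conc) +
      outer(spec$stain_matrix["eosin", ], e_conc)
    img <- exp(-od)
    img[img < 0] <- 0; img[img > 1] <- 1
    images[, , , i] <- img
  }
  list(images = images, labels = labels,
       classes = c("benign", "malignant"))
}

#' Write / read a dataset as PNG tiles in class-named directories
#'
#' `write_dataset` creates one subdirectory per class, writes each tile
#' as a PNG and a `labels.csv` manifest (columns `file`, `label`);
#' `read_dataset` loads that layout back (any directory tree whose
#' first level is class names works, so real data can be dropped in).
#'
#' @param data a list with `images`, `labels`, `classes` (as produced
#'   by [generate_dataset()]).
#' @param dir target directory.
#' @param force overwrite an existing non-empty directory.
#' @return `write_dataset`: the directory, invisibly; `read_dataset`:
#'   a list with `images`, `labels`, `classes`.
#' @export
write_dataset <- function(data, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !isTRUE(force))
    stopf("directory '%s' exists and is not empty (use force)", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(data$images)[4L]
  files <- character(n)
  for (cl in seq_along(data$classes))
    dir.create(file.path(dir, data$classes[cl]), showWarnings = FALSE)
  for (i in seq_len(n)) {
    cl <- data$classes[data$labels[i]]
    files[i] <- file.path(cl, sprintf("img_%04d.png", i))
    png::writePNG(aperm(data$images[, , , i], c(2L, 3L, 1L)),
                  file.path(dir, files[i]))
  }
  utils::write.csv(data.frame(file = files, label = data$classes[data$labels]),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @param image_size optional side length images are resized to on read.
#' @export
read_dataset <- function(dir, image_size = NULL) {
  if (!dir.exists(dir)) stopf("dataset directory '%s' does not exist", dir)
  classes <- sort(list.dirs(dir, full.names = FALSE, recursive = FALSE))
  if (length(classes) == 0L) stopf("no class subdirectories in '%s'", dir)
  files <- list(); labels <- integer(0)
  for (cl in seq_along(classes)) {
    fs <- list.files(file.path(dir, classes[cl]), pattern = "\\.png$",
                     full.names = TRUE)
    files <- c(files, as.list(fs))
    labels <- c(labels, rep(cl, length(fs)))
  }
  if (length(files) == 0L) stopf("no PNG tiles found under '%s'", dir)
  first <- png::readPNG(files[[1L]])
  S <- image_size %||% dim(first)[1L]
  images <- array(0, c(3L, S, S, length(files)))
  for (i in seq_along(files)) {
    a <- png::readPNG(files[[i]])
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
    img <- aperm(a[, , 1:3, drop = FALSE], c(3L, 1L, 2L))
    if (dim(img)[2L] != S) img <- bilinear_resize(img, S, S)
    images[, , , i] <- img
  }
  list(images = images, labels = labels, classes = classes)
}

#' Binary grouping of the EBHI 200x benchmark categories
#'
#' Sums the published per-category image counts of the 200x subset into
#' the benign/malignant super-classes (Normal, Polyp and Low-grade IN
#' vs High-grade IN and Adenocarcinoma).  The per-category table ships
#' with the package as a plain-text file.
#'
#' @return list with the per-category `table` and the `benign`,
#'   `malignant` and `total` counts.
#' @export
ebhi_binary_counts <- function() {
  path <- system.file("extdata", "ebhi_200x_counts.csv", package = "fgar",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  benign <- sum(tab$images[tab$binary_label == "benign"])
  malignant <- sum(tab$images[tab$binary_label == "malignant"])
  list(table = tab, benign = benign, malignant = malignant,
       total = benign + malignant)
}
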