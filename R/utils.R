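#' @keywords internal
#' @useDynLib fgar, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Small numerical helpers shared across the encoder, the shallow
## classifiers and the synthetic generator.  All operate on plain base-R
## matrices/arrays; row-wise ops are vectorised (no per-row loops).

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

## GELU, tanh approximation (the convention of most transformer
## implementations; cheaper than the exact erf form).  The forward
## returns the tanh term so the backward can reuse it.
gelu_fwd <- function(x) gelu_fwd_cpp(x)
gelu <- function(x) {
  if (!is.matrix(x)) {
    d <- dim(x)
    y <- gelu_fwd_cpp(matrix(x))$y
    dim(y) <- d %||% NULL
    if (is.null(d)) y <- as.vector(y)
    return(y)
  }
  gelu_fwd_cpp(x)$y
}
gelu_grad <- function(x, t) gelu_grad_cpp(x, t)

## Row-wise softmax with max-subtraction for stability.
softmax_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

## Truncated normal (+-2 sd) via inverse-CDF; deterministic under the
## current RNG state.  Standard transformer weight init.
rtnorm02 <- function(n, sd = 0.02) {
  lo <- stats::pnorm(-2); hi <- stats::pnorm(2)
  stats::qnorm(lo + stats::runif(n) * (hi - lo)) * sd
}

## Multiply each row of x (n x d) by the length-d vector v without
## forming diag(v).
scale_cols <- function(x, v) x * rep(v, each = nrow(x))

## --- Layer normalisation (last-dim, per row) --------------------------

layer_norm_fwd <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  istd <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * istd
  list(y = scale_cols(xhat, g) + rep(b, each = nrow(x)),
       xhat = xhat, istd = istd)
}

layer_norm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- scale_cols(dy, g)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$istd
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

## --- Batched 2-D DFT --------------------------------------------------
## Grids are stacked along the third dim of an (H, W, M) array.  The 2-D
## DFT of each slice is Fh %*% X %*% Fw with symmetric DFT matrices, so
## both sides reduce to two large complex matmuls.  Convention:
## unnormalised forward, 1/(H*W) on the inverse (matches stats::fft).

dft_matrix <- function(n, inverse = FALSE) {
  s <- if (inverse) 2i else -2i
  k <- 0:(n - 1)
  exp(s * pi * outer(k, k) / n)
}

bdft2 <- function(a, inverse = FALSE) {
  d <- dim(a)
  h <- d[1L]; w <- d[2L]; m <- if (length(d) == 3L) d[3L] else 1L
  fh <- dft_matrix(h, inverse)
  fw <- if (w == h) fh else dft_matrix(w, inverse)
  y <- fh %*% matrix(a, h, w * m)            # transform rows of each grid
  y <- array(y, c(h, w, m))
  y <- aperm(y, c(2L, 1L, 3L))
  y <- fw %*% matrix(y, w, h * m)            # transform columns
  y <- aperm(array(y, c(w, h, m)), c(2L, 1L, 3L))
  if (inverse) y <- y / (h * w)
  if (length(d) == 2L) dim(y) <- d
  y
}

## ISO-timestamped message to stderr (CLI logging).
log_msg <- function(...) {
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), sprintf(...))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

## Stratified index split: returns list(train, test) keeping class
## proportions; deterministic under seed.
stratified_split <- function(labels, test_fraction, seed) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  test <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    k <- max(1L, round(length(idx) * test_fraction))
    test <- c(test, sample(idx, k))
  }
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

## Save/restore the global RNG state so helpers with their own seed do
## not perturb a caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}
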