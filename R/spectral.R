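## Spectral branch primitives: patch-grid re-layout, the 2-D Fourier
## transform pair over the patch grid, and squeeze-and-excitation
## channel gating computed from spectral magnitudes.
##
## Conventions (fixed and relied upon by tests):
##  * full complex spectrum, zero frequency at index (1, 1);
##  * unnormalised forward transform, 1/(Hp*Wp) on the inverse
##    (same as stats::fft / stats::fft(inverse=TRUE)/n);
##  * channel descriptor = mean magnitude over all coefficients.

#' Reshape patch tokens to their 2-D grid layout
#'
#' The N patch tokens of a token sequence are stored row-major over the
#' patch grid: token k (1-based) sits at grid cell
#' (row = (k-1) %/% Wp + 1, col = (k-1) %% Wp + 1).  `to_patch_grid`
#' re-lays the N x D token matrix out as a channel-first D x Hp x Wp
#' array (the domain of the 2-D Fourier transform);
#' `from_patch_grid` is its exact inverse.
#'
#' @param tokens numeric matrix N x D of patch tokens (no class token).
#' @param grid_shape integer vector `c(Hp, Wp)` with `Hp * Wp == N`.
#' @return `to_patch_grid`: numeric array D x Hp x Wp.
#' @export
to_patch_grid <- function(tokens, grid_shape) {
  tokens <- as.matrix(tokens)
  hp <- as.integer(grid_shape[1L]); wp <- as.integer(grid_shape[2L])
  if (nrow(tokens) != hp * wp)
    stopf("token count %d does not match grid %d x %d",
          nrow(tokens), hp, wp)
  a <- array(tokens, c(wp, hp, ncol(tokens)))  # [col, row, channel]
  aperm(a, c(3L, 2L, 1L))
}

#' @rdname to_patch_grid
#' @param grid numeric array D x Hp x Wp.
#' @return `from_patch_grid`: numeric matrix N x D.
#' @export
from_patch_grid <- function(grid) {
  d <- dim(grid)
  if (length(d) != 3L) stopf("grid must be a D x Hp x Wp array")
  a <- aperm(grid, c(3L, 2L, 1L))              # [col, row, channel]
  matrix(a, d[2L] * d[3L], d[1L])
}

#' Per-channel 2-D Fourier transform of a patch grid
#'
#' `fft2` applies an unnormalised 2-D DFT to each channel slice of a
#' D x Hp x Wp patch grid and returns the full complex spectrum (same
#' shape); `ifft2` inverts it with the 1/(Hp*Wp) normalisation and
#' returns the real grid.  A spectrum whose inverse has imaginary
#' residue above `imag_tol` (relative to the reconstruction magnitude)
#' signals corruption and raises an error.
#'
#' @param grid real array D x Hp x Wp.
#' @return `fft2`: complex array D x Hp x Wp.
#' @export
fft2 <- function(grid) {
  if (!all(is.finite(grid))) stopf("non-finite values in patch grid")
  d <- dim(grid)
  a <- bdft2(aperm(grid, c(2L, 3L, 1L)))       # (Hp, Wp, D) slices
  aperm(a, c(3L, 1L, 2L))
}

#' @rdname fft2
#' @param spectrum complex array D x Hp x Wp.
#' @param imag_tol maximum tolerated relative imaginary residue.
#' @return `ifft2`: real array D x Hp x Wp.
#' @export
ifft2 <- function(spectrum, imag_tol = 1e-5) {
  d <- dim(spectrum)
  if (length(d) != 3L) stopf("spectrum must be a D x Hp x Wp array")
  a <- bdft2(aperm(spectrum, c(2L, 3L, 1L)), inverse = TRUE)
  a <- aperm(a, c(3L, 1L, 2L))
  scale <- max(abs(Re(a)), 1)
  if (max(abs(Im(a))) > imag_tol * scale)
    stopf("imaginary residue %.3g exceeds tolerance %.3g: corrupted spectrum",
          max(abs(Im(a))), imag_tol * scale)
  Re(a)
}

#' Squeeze-and-excitation gate from spectral magnitudes
#'
#' Compresses a spectrum to a per-channel descriptor (the mean magnitude
#' of its coefficients — phase-invariant and homogeneous of degree one),
#' then passes it through the two-layer excitation bottleneck
#' `sigmoid(W2 %*% relu(W1 %*% d + b1) + b2)`.  Gates are strictly in
#' (0, 1).
#'
#' @param spectrum complex array D x Hp x Wp (or a real array for the
#'   spatial-domain variant used by the B2 ablation, where the
#'   descriptor is the mean absolute value).
#' @param se_params list with `W1` (D x Dr), `b1` (Dr), `W2` (Dr x D),
#'   `b2` (D).
#' @return numeric gate vector of length D, entries in (0, 1).
#' @export
se_gate <- function(spectrum, se_params) {
  d <- dim(spectrum)
  desc <- rowMeans(matrix(Mod(spectrum), d[1L], d[2L] * d[3L]))
  se_excite(matrix(desc, 1L), se_params)$gate[1L, ]
}

## Shared excitation bottleneck on a B x D descriptor matrix.
se_excite <- function(desc, p) {
  if (ncol(desc) != nrow(p$W1))
    stopf("descriptor length %d does not match SE input %d",
          ncol(desc), nrow(p$W1))
  h1 <- pmax(desc %*% p$W1 + rep(p$b1, each = nrow(desc)), 0)
  gate <- sigmoid(h1 %*% p$W2 + rep(p$b2, each = nrow(desc)))
  list(gate = gate, h1 = h1)
}

#' Rescale a spectrum channel-wise
#'
#' Multiplies every coefficient of channel c by the real scalar
#' `gate[c]`.  Because the gate is real and uniform over frequencies,
#' this commutes with the inverse transform: gating then inverting
#' equals inverting then scaling each channel's spatial slice.
#'
#' @param spectrum complex array D x Hp x Wp.
#' @param gate numeric vector of length D.
#' @return complex array D x Hp x Wp.
#' @export
apply_gate <- function(spectrum, gate) {
  d <- dim(spectrum)
  if (length(gate) != d[1L])
    stopf("gate length %d does not match channel count %d",
          length(gate), d[1L])
  spectrum * gate  # gate recycles along the first (channel) dimension
}
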