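## Image helpers on channel-first (3, S, S) arrays with values in [0, 1].
## Index convention: [channel, row (y), column (x)].

luma <- function(img) {
  0.299 * img[1L, , ] + 0.587 * img[2L, , ] + 0.114 * img[3L, , ]
}

#' Rotate an image by quarter turns
#'
#' @param img numeric array 3 x S x S.
#' @param k number of 90-degree counter-clockwise turns (0..3).
#' @return rotated 3 x S x S array.
#' @export
rotate90 <- function(img, k = 1L) {
  k <- as.integer(k) %% 4L
  if (k == 0L) return(img)
  for (i in seq_len(k)) {
    # ccw: new[y, x] = old[x, S + 1 - y]
    img <- aperm(img, c(1L, 3L, 2L))[, , dim(img)[2L]:1L, drop = FALSE]
  }
  img
}

flip_h <- function(img) img[, , dim(img)[3L]:1L, drop = FALSE]  # mirror columns
flip_v <- function(img) img[, dim(img)[2L]:1L, , drop = FALSE]  # mirror rows

#' Bilinear resize of a channel-first image
#'
#' @param img numeric array 3 x H x W (or a single H x W matrix).
#' @param out_h,out_w output size in pixels (`out_w` defaults to `out_h`).
#' @return resized array (same channel layout).
#' @export
bilinear_resize <- function(img, out_h, out_w = out_h) {
  single <- is.matrix(img)
  if (single) { dim(img) <- c(1L, dim(img)) }
  d <- dim(img)
  h <- d[2L]; w <- d[3L]
  if (h == out_h && w == out_w) {
    return(if (single) img[1L, , ] else img)
  }
  # align-corners = FALSE sampling (pixel-centre mapping)
  sy <- pmin(pmax((seq_len(out_h) - 0.5) * h / out_h - 0.5, 0), h - 1)
  sx <- pmin(pmax((seq_len(out_w) - 0.5) * w / out_w - 0.5, 0), w - 1)
  y0 <- pmin(floor(sy), h - 1L); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(floor(sx), w - 1L); x1 <- pmin(x0 + 1, w - 1)
  wy <- sy - y0; wx <- sx - x0
  out <- array(0, c(d[1L], out_h, out_w))
  for (c in seq_len(d[1L])) {
    m <- img[c, , ]
    a <- m[y0 + 1L, x0 + 1L, drop = FALSE] * (1 - wy) +
         m[y1 + 1L, x0 + 1L, drop = FALSE] * wy
    b <- m[y0 + 1L, x1 + 1L, drop = FALSE] * (1 - wy) +
         m[y1 + 1L, x1 + 1L, drop = FALSE] * wy
    out[c, , ] <- a * rep(1 - wx, each = out_h) + b * rep(wx, each = out_h)
  }
  if (single) out[1L, , ] else out
}

## Hue rotation via the YIQ chroma plane; theta in turns (1 = full
## rotation), so a +-0.02 "hue shift" rotates the chroma phase by
## +-7.2 degrees.
hue_rotate <- function(img, theta) {
  a <- cos(2 * pi * theta); b <- sin(2 * pi * theta)
  toyiq <- matrix(c(0.299, 0.587, 0.114,
                    0.596, -0.274, -0.322,
                    0.211, -0.523, 0.312), 3L, byrow = TRUE)
  rot <- matrix(c(1, 0, 0, 0, a, -b, 0, b, a), 3L, byrow = TRUE)
  m <- solve(toyiq) %*% rot %*% toyiq
  d <- dim(img)
  out <- m %*% matrix(img, 3L)
  dim(out) <- d
  out
}
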