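## The Fourier-guided attention encoder.
##
## Tokens flow through the network as a (B*T) x D matrix, sample-major
## (rows (b-1)*T + 1 .. b*T hold sample b; row (b-1)*T + 1 is its class
## token).  The spectral branch re-lays patch tokens out as
## (Hp, Wp, B*D) grid stacks so the per-channel 2-D DFT reduces to two
## large complex matmuls (see bdft2 in utils.R).

#' Create an encoder model
#'
#' Initialises all learnable parameters of the configured encoder:
#' patch projection, class token, positional embeddings, per-block
#' layer norms, SE bottlenecks, attention and MLP weights, and the
#' classification head.  Projection weights are drawn from a truncated
#' normal (sd 0.02, clipped at 2 sd); biases start at zero, norm gains
#' at one, and the optional spectral filter at the identity mask.
#'
#' @param config an [fga_config()].
#' @param seed integer seed making the initialisation reproducible.
#' @return an object of class `fga_model`: `list(config, params)`.
#' @export
fga_model <- function(config = fga_config(), seed = 1L) {
  stopifnot(inherits(config, "fga_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  D <- config$embed_dim; N <- config$n_patches
  pdim <- 3L * config$patch_size^2
  Dm <- as.integer(round(config$mlp_ratio * D))
  Dr <- config$se_hidden
  tn <- function(nr, nc) matrix(rtnorm02(nr * nc), nr, nc)
  p <- list(
    embed_W = tn(pdim, D), embed_b = numeric(D),
    cls = rtnorm02(D), pos = tn(N + 1L, D))
  spectral_on <- config$use_fft || config$use_se
  p$blocks <- lapply(seq_len(config$depth), function(l) {
    b <- list()
    if (spectral_on) { b$ln1_g <- rep(1, D); b$ln1_b <- numeric(D) }
    if (config$use_se) {
      # Fan-in (LeCun) scaling: with the generic 0.02 init the sigmoid
      # gates sit at 0.5 with ~1e-4 spread and the SE branch is inert
      # over short training budgets.
      b$se_W1 <- matrix(stats::rnorm(D * Dr, sd = 1 / sqrt(D)), D, Dr)
      b$se_b1 <- numeric(Dr)
      b$se_W2 <- matrix(stats::rnorm(Dr * D, sd = 1 / sqrt(Dr)), Dr, D)
      b$se_b2 <- numeric(D)
    }
    if (config$use_fft && config$use_spectral_filter) {
      gs <- config$grid_shape
      b$filt_re <- array(1, c(gs[1L], gs[2L], D))
      b$filt_im <- array(0, c(gs[1L], gs[2L], D))
    }
    b$ln2_g <- rep(1, D); b$ln2_b <- numeric(D)
    b$W_qkv <- tn(D, 3L * D); b$b_qkv <- numeric(3L * D)
    b$W_o <- tn(D, D); b$b_o <- numeric(D)
    b$ln3_g <- rep(1, D); b$ln3_b <- numeric(D)
    b$W_m1 <- tn(D, Dm); b$b_m1 <- numeric(Dm)
    b$W_m2 <- tn(Dm, D); b$b_m2 <- numeric(D)
    b
  })
  if (config$final_norm) { p$lnf_g <- rep(1, D); p$lnf_b <- numeric(D) }
  p$head_W <- tn(D, config$num_classes)
  p$head_b <- numeric(config$num_classes)
  structure(list(config = config, params = p), class = "fga_model")
}

#' @export
print.fga_model <- function(x, ...) {
  np <- sum(unlist(rapply(x$params, length, how = "list")))
  cat(sprintf("<fga_model> %s variant, %s parameters\n",
              variant_name(x$config), format(np, big.mark = ",")))
  print(x$config)
  invisible(x)
}

## Linear index map from one (3, S, S) image vector to the N x (3*P^2)
## patch matrix.  Flatten order inside a patch: pixels row-major,
## the 3 channels contiguous per pixel (fixed for checkpoint
## portability).
.index_memo <- new.env(parent = emptyenv())

patch_index <- function(config) {
  key <- sprintf("pi_%d_%d", config$image_size, config$patch_size)
  memo <- get0(key, envir = .index_memo)
  if (!is.null(memo)) return(memo)
  P <- config$patch_size; S <- config$image_size
  wp <- config$grid_shape[2L]
  k <- seq_len(config$n_patches)
  gy <- (k - 1L) %/% wp; gx <- (k - 1L) %% wp
  a <- rep(rep(seq_len(P), each = P), each = 3L)   # pixel row
  b <- rep(rep(seq_len(P), times = P), each = 3L)  # pixel col
  ch <- rep(1:3, times = P * P)
  # idx[k, j] into a (3, S, S) array, column-major
  y <- outer(gy * P, a, "+")                       # N x 3P^2 pixel rows
  x <- outer(gx * P, b, "+")
  out <- matrix(rep(ch, each = length(k)), length(k)) +
    3L * (y - 1L) + 3L * S * (x - 1L)
  assign(key, out, envir = .index_memo)
  out
}

## Coerce input to a (3, S, S, B) array, validating the spatial size.
as_image_batch <- function(images, config) {
  d <- dim(images)
  S <- config$image_size
  if (length(d) == 3L) { dim(images) <- c(d, 1L); d <- dim(images) }
  if (length(d) != 4L || d[1L] != 3L || d[2L] != d[3L])
    stopf("images must be a 3 x S x S (x B) array, got %s",
          paste(d, collapse = " x "))
  if (d[2L] != S)
    stopf("image size %d x %d does not match configured %d x %d",
          d[2L], d[3L], S, S)
  if (!all(is.finite(images))) stopf("non-finite image values")
  images
}

#' Tokenize an image: patch embedding, class token, positional encoding
#'
#' Cuts the image into non-overlapping P x P patches ((S/P)^2 of them),
#' flattens each patch (pixels row-major, channels last within each
#' pixel) and projects it linearly to D dimensions, prepends the
#' learnable class token and adds the learnable positional embedding
#' covering all N + 1 rows.
#'
#' @param image numeric array 3 x S x S with finite values.
#' @param model an [fga_model()] supplying the embedding parameters.
#' @return an object of class `fga_tokens`: list with `tokens`
#'   ((N+1) x D matrix, row 1 the class token) and `grid_shape`.
#' @export
patch_embed <- function(image, model) {
  stopifnot(inherits(model, "fga_model"))
  cfg <- model$config
  images <- as_image_batch(image, cfg)
  x <- embed_batch(images, cfg, model$params)
  structure(list(tokens = x$X[seq_len(cfg$n_patches + 1L), , drop = FALSE],
                 grid_shape = cfg$grid_shape),
            class = "fga_tokens")
}

## Batched embedding: returns X ((B*T) x D) plus layout indices.
embed_batch <- function(images, cfg, p) {
  B <- dim(images)[4L]
  N <- cfg$n_patches; T <- N + 1L; D <- cfg$embed_dim
  idx <- patch_index(cfg)
  nim <- 3L * cfg$image_size^2
  Xp <- matrix(0, B * N, ncol(idx))
  iv <- as.vector(idx)
  for (b in seq_len(B)) {
    v <- images[, , , b]
    Xp[((b - 1L) * N + 1L):(b * N), ] <- v[iv]
  }
  Zp <- Xp %*% p$embed_W + rep(p$embed_b, each = B * N)
  X <- matrix(0, B * T, D)
  icls <- seq(1L, B * T, by = T)
  ipatch <- setdiff(seq_len(B * T), icls)
  X[icls, ] <- matrix(p$cls, B, D, byrow = TRUE)
  X[ipatch, ] <- Zp
  X <- X + p$pos[rep(seq_len(T), times = B), ]
  list(X = X, icls = icls, ipatch = ipatch, Xp = Xp)
}

## Permutation mapping patch-token rows (B*N x D) onto grid stacks
## (Hp, Wp, B*D); grid m = (b-1)*D + c.  A bijection, so the inverse
## scatter uses the same index vector.
grid_perm <- function(B, cfg) {
  hp <- cfg$grid_shape[1L]; wp <- cfg$grid_shape[2L]
  D <- cfg$embed_dim; N <- cfg$n_patches
  key <- sprintf("gp_%d_%d_%d_%d", B, hp, wp, D)
  memo <- get0(key, envir = .index_memo)
  if (!is.null(memo)) return(memo)
  ys <- rep(seq_len(hp), times = wp * D * B)
  xs <- rep(rep(seq_len(wp), each = hp), times = D * B)
  cs <- rep(rep(seq_len(D), each = hp * wp), times = B)
  bs <- rep(seq_len(B), each = hp * wp * D)
  out <- ((bs - 1L) * N + (ys - 1L) * wp + xs) + (cs - 1L) * (B * N)
  assign(key, out, envir = .index_memo)
  out
}

## ---- spectral refinement stage (batched) -----------------------------

spectral_branch_fwd <- function(Tn, blk, cfg, B) {
  hp <- cfg$grid_shape[1L]; wp <- cfg$grid_shape[2L]
  K <- hp * wp; D <- cfg$embed_dim; N <- cfg$n_patches
  cache <- list()
  if (cfg$use_fft) {
    PI <- grid_perm(B, cfg)
    grids <- array(Tn[PI], c(hp, wp, B * D))
    Fc <- bdft2(grids)
    if (cfg$use_spectral_filter) {
      phi <- complex(real = blk$filt_re, imaginary = blk$filt_im)
      dim(phi) <- c(hp, wp, D)
      phim <- phi[, , rep(seq_len(D), times = B), drop = FALSE]
      Ff <- phim * Fc
      cache$Fc <- Fc
    } else Ff <- Fc
    if (cfg$use_se) {
      dm <- colMeans(matrix(Mod(Ff), K, B * D))
      desc <- t(matrix(dm, D, B))
      ex <- se_excite(desc, list(W1 = blk$se_W1, b1 = blk$se_b1,
                                 W2 = blk$se_W2, b2 = blk$se_b2))
      gv <- as.vector(t(ex$gate))            # channel-fastest, matches m
      gated <- Ff * rep(gv, each = K)
      cache$desc <- desc; cache$gate <- ex$gate; cache$h1 <- ex$h1
    } else gated <- Ff
    Sg <- bdft2(gated, inverse = TRUE)
    S <- matrix(0, B * N, D)
    S[PI] <- Re(Sg)
    cache$Ff <- Ff; cache$PI <- PI
  } else {
    # B2: SE gate from spatial channel statistics (mean |value|)
    grp <- rep(seq_len(B), each = N)
    desc <- rowsum(abs(Tn), grp, reorder = TRUE) / N
    ex <- se_excite(desc, list(W1 = blk$se_W1, b1 = blk$se_b1,
                               W2 = blk$se_W2, b2 = blk$se_b2))
    S <- Tn * ex$gate[grp, , drop = FALSE]
    cache$desc <- desc; cache$gate <- ex$gate; cache$h1 <- ex$h1
    cache$grp <- grp
  }
  cache$Tn <- Tn
  list(S = S, cache = cache)
}

## ---- multi-head self-attention (pre-norm, residual) ------------------

attention_fwd <- function(X, blk, cfg, B) {
  H <- cfg$num_heads
  T <- nrow(X) %/% B
  ln <- layer_norm_fwd(X, blk$ln2_g, blk$ln2_b)
  QKV <- ln$y %*% blk$W_qkv + rep(blk$b_qkv, each = nrow(X))
  at <- attn_fwd_cpp(QKV, B, T, H)
  out <- at$O %*% blk$W_o + rep(blk$b_o, each = nrow(X))
  list(Y = X + out, ln = ln, QKV = QKV, A = at$A, O = at$O)
}

## ---- feed-forward stage (pre-norm, residual) -------------------------

mlp_fwd <- function(X, blk, cfg, train = FALSE) {
  ln <- layer_norm_fwd(X, blk$ln3_g, blk$ln3_b)
  H1 <- ln$y %*% blk$W_m1 + rep(blk$b_m1, each = nrow(X))
  gf <- gelu_fwd(H1)
  Hg <- gf$y
  mask <- NULL
  if (train && cfg$drop_rate > 0) {
    mask <- matrix(stats::rbinom(length(Hg), 1L, 1 - cfg$drop_rate),
                   nrow(Hg)) / (1 - cfg$drop_rate)
    Hg <- Hg * mask
  }
  out <- Hg %*% blk$W_m2 + rep(blk$b_m2, each = nrow(X))
  list(Y = X + out, ln = ln, H1 = H1, Hg = Hg, gt = gf$t, mask = mask)
}

## ---- full forward ----------------------------------------------------

## mode "train" keeps every intermediate needed by fga_backward.
forward_batch <- function(model, images, mode = "infer") {
  cfg <- model$config; p <- model$params
  images <- as_image_batch(images, cfg)
  B <- dim(images)[4L]
  T <- cfg$n_patches + 1L
  emb <- embed_batch(images, cfg, p)
  X <- emb$X
  train <- identical(mode, "train")
  spectral_on <- cfg$use_fft || cfg$use_se
  caches <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    blk <- p$blocks[[l]]
    cache <- list()
    if (spectral_on) {
      Tp <- X[emb$ipatch, , drop = FALSE]
      ln1 <- layer_norm_fwd(Tp, blk$ln1_g, blk$ln1_b)
      sb <- spectral_branch_fwd(ln1$y, blk, cfg, B)
      X[emb$ipatch, ] <- Tp + sb$S
      cache$ln1 <- ln1; cache$sb <- sb$cache
    }
    at <- attention_fwd(X, blk, cfg, B)
    cache$attn_in <- X
    X <- at$Y
    ml <- mlp_fwd(X, blk, cfg, train = train)
    cache$attn <- at[c("ln", "QKV", "A", "O")]
    cache$mlp_in <- X
    cache$mlp <- ml[c("ln", "H1", "Hg", "gt", "mask")]
    X <- ml$Y
    if (anyNA(X) || any(is.infinite(X)))
      stopf("non-finite activations in encoder block %d", l)
    caches[[l]] <- cache
  }
  Zcls <- X[emb$icls, , drop = FALSE]
  lnf <- NULL
  feat <- Zcls
  if (cfg$final_norm) {
    lnf <- layer_norm_fwd(Zcls, p$lnf_g, p$lnf_b)
    feat <- lnf$y
  }
  logits <- feat %*% p$head_W + rep(p$head_b, each = B)
  probs <- softmax_rows(logits)
  out <- list(logits = logits, probs = probs, features = feat, B = B)
  if (train)
    out$cache <- list(emb = emb, blocks = caches, lnf = lnf,
                      Zcls = Zcls, Xp = emb$Xp)
  out
}

#' Run the encoder end-to-end
#'
#' `fga_forward` returns class probabilities (softmax over the affine
#' head applied to the final class token); `fga_extract` returns the
#' final class token itself (after the optional final layer norm,
#' before the head) — the transferable feature used by the downstream
#' shallow-classifier protocol.  Both are deterministic in evaluation
#' mode.
#'
#' @param model an [fga_model()].
#' @param images array 3 x S x S (single image) or 3 x S x S x B.
#' @return `fga_forward`: numeric matrix B x C of probabilities, rows
#'   summing to one (a vector for a single image); `fga_extract`: B x D
#'   feature matrix (vector for a single image).
#' @export
fga_forward <- function(model, images) {
  stopifnot(inherits(model, "fga_model"))
  out <- forward_batch(model, images)
  if (length(dim(images)) == 3L) drop(out$probs) else out$probs
}

#' @rdname fga_forward
#' @export
fga_extract <- function(model, images) {
  stopifnot(inherits(model, "fga_model"))
  out <- forward_batch(model, images)
  if (length(dim(images)) == 3L) drop(out$features) else out$features
}

#' @export
predict.fga_model <- function(object, images,
                              type = c("probs", "feature"), ...) {
  type <- match.arg(type)
  if (type == "probs") fga_forward(object, images)
  else fga_extract(object, images)
}

## ---- single-sequence public block operations -------------------------

check_tokens <- function(tokens, config) {
  if (inherits(tokens, "fga_tokens")) tokens <- tokens$tokens
  tokens <- as.matrix(tokens)
  if (nrow(tokens) != config$n_patches + 1L)
    stopf("token sequence has %d rows, expected %d (N + 1)",
          nrow(tokens), config$n_patches + 1L)
  if (ncol(tokens) != config$embed_dim)
    stopf("token width %d does not match embed_dim %d",
          ncol(tokens), config$embed_dim)
  tokens
}

#' Fourier-guided refinement plus self-attention for one token sequence
#'
#' The spectral refinement stage of one encoder block: the class token
#' (row 1) is split off; the patch tokens are layer-normalised,
#' re-laid out on the patch grid, pushed through the
#' FFT -> SE gate -> IFFT branch (subject to the `use_fft`/`use_se`
#' flags) and added back residually; the class token is re-prepended
#' and pre-norm multi-head self-attention with residual is applied to
#' all N + 1 tokens.
#'
#' @param tokens an `fga_tokens` object or (N+1) x D matrix.
#' @param block_params one element of `model$params$blocks`.
#' @param config the model's [fga_config()].
#' @return (N+1) x D token matrix.
#' @export
far_refine <- function(tokens, block_params, config) {
  X <- check_tokens(tokens, config)
  if (!all(is.finite(X))) stopf("non-finite activations in token input")
  if (config$use_fft || config$use_se) {
    Tp <- X[-1L, , drop = FALSE]
    ln1 <- layer_norm_fwd(Tp, block_params$ln1_g, block_params$ln1_b)
    sb <- spectral_branch_fwd(ln1$y, block_params, config, 1L)
    X[-1L, ] <- Tp + sb$S
  }
  attention_fwd(X, block_params, config, 1L)$Y
}

#' One full encoder block for a single token sequence
#'
#' [far_refine()] followed by the pre-norm two-layer GELU MLP (hidden
#' width `mlp_ratio * D`) with residual; the (N+1) x D shape is
#' preserved.
#'
#' @inheritParams far_refine
#' @return (N+1) x D token matrix.
#' @export
encoder_block <- function(tokens, block_params, config) {
  X <- far_refine(tokens, block_params, config)
  mlp_fwd(X, block_params, config)$Y
}
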