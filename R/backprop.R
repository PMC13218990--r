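## Reverse-mode gradients for the encoder, written against the caches
## produced by forward_batch(..., mode = "train").
##
## Complex-gradient convention for the spectral branch: for a complex
## intermediate Y we store g with dL = sum Re(Conj(g) * dY).  With the
## unnormalised-forward / (1/K)-inverse DFT pair this gives, for real
## input x and S = Re(IFFT(Y)):
##   dL/dY = DFT2(dS) / K,
## and for F = DFT2(x):
##   dL/dx = Re(DFT2(Conj(dL/dF))).
## The magnitude descriptor d = mean|F| contributes
##   dL/dF += (dd / K) * F / |F|   (zero where |F| ~ 0).

zeros_like <- function(x) { y <- x; y[] <- 0; y }

## Elementwise walk over two identically shaped nested parameter lists.
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, tree_map, f = f)
    names(out) <- names(a)
    out
  } else f(a)
}

spectral_branch_bwd <- function(dS, blk, cfg, B, cache) {
  hp <- cfg$grid_shape[1L]; wp <- cfg$grid_shape[2L]
  K <- hp * wp; D <- cfg$embed_dim; N <- cfg$n_patches
  g <- list()
  se_bwd <- function(dgate, cache) {
    dz2 <- dgate * cache$gate * (1 - cache$gate)
    g$se_W2 <<- crossprod(cache$h1, dz2)
    g$se_b2 <<- colSums(dz2)
    dh1 <- tcrossprod(dz2, blk$se_W2) * (cache$h1 > 0)
    g$se_W1 <<- crossprod(cache$desc, dh1)
    g$se_b1 <<- colSums(dh1)
    tcrossprod(dh1, blk$se_W1)         # d descriptor, B x D
  }
  if (cfg$use_fft) {
    PI <- cache$PI
    dSg <- array(dS[PI], c(hp, wp, B * D))
    dY <- bdft2(dSg) / K
    if (cfg$use_se) {
      gv <- as.vector(t(cache$gate))
      dgm <- colSums(matrix(Re(Conj(dY) * cache$Ff), K, B * D))
      dgate <- t(matrix(dgm, D, B))
      dFf <- dY * rep(gv, each = K)
      ddesc <- se_bwd(dgate, cache)
      mag <- pmax(Mod(cache$Ff), 1e-12)
      phase <- cache$Ff / mag
      live <- Mod(cache$Ff) > 1e-12
      dd_v <- as.vector(t(ddesc)) / K
      dFf <- dFf + phase * live * rep(dd_v, each = K)
    } else dFf <- dY
    if (cfg$use_spectral_filter) {
      phi <- complex(real = blk$filt_re, imaginary = blk$filt_im)
      dim(phi) <- c(hp, wp, D)
      cm <- Conj(dFf) * cache$Fc
      grp <- rep(seq_len(D), times = B)
      g$filt_re <- array(t(rowsum(t(matrix(Re(cm), K, B * D)), grp)),
                         c(hp, wp, D))
      g$filt_im <- array(-t(rowsum(t(matrix(Im(cm), K, B * D)), grp)),
                         c(hp, wp, D))
      dFc <- Conj(phi[, , grp, drop = FALSE]) * dFf
    } else dFc <- dFf
    dTn_g <- Re(bdft2(Conj(dFc)))
    dTn <- matrix(0, B * N, D)
    dTn[] <- 0
    dTn[PI] <- dTn_g
  } else {
    grp <- cache$grp
    dgate <- rowsum(dS * cache$Tn, grp, reorder = TRUE)
    dTn <- dS * cache$gate[grp, , drop = FALSE]
    ddesc <- se_bwd(dgate, cache)
    dTn <- dTn + sign(cache$Tn) * ddesc[grp, , drop = FALSE] / N
  }
  list(dTn = dTn, grads = g)
}

attention_bwd <- function(dY, blk, cfg, B, cache, Xin) {
  H <- cfg$num_heads
  T <- nrow(dY) %/% B
  dX <- dY                                  # residual path
  dW_o <- crossprod(cache$O, dY)
  db_o <- colSums(dY)
  dO <- tcrossprod(dY, blk$W_o)
  QKV <- cache$QKV
  dQKV <- attn_bwd_cpp(dO, QKV, cache$A, B, T, H)
  dXn <- tcrossprod(dQKV, blk$W_qkv)
  dW_qkv <- crossprod(cache$ln$y, dQKV)
  db_qkv <- colSums(dQKV)
  lb <- layer_norm_bwd(dXn, cache$ln, blk$ln2_g)
  dX <- dX + lb$dx
  list(dX = dX,
       grads = list(W_qkv = dW_qkv, b_qkv = db_qkv, W_o = dW_o,
                    b_o = db_o, ln2_g = lb$dg, ln2_b = lb$db))
}

mlp_bwd <- function(dY, blk, cfg, cache) {
  dX <- dY
  dHg <- tcrossprod(dY, blk$W_m2)
  dW_m2 <- crossprod(cache$Hg, dY)
  db_m2 <- colSums(dY)
  if (!is.null(cache$mask)) dHg <- dHg * cache$mask
  dH1 <- dHg * gelu_grad(cache$H1, cache$gt)
  dW_m1 <- crossprod(cache$ln$y, dH1)
  db_m1 <- colSums(dH1)
  dXn <- tcrossprod(dH1, blk$W_m1)
  lb <- layer_norm_bwd(dXn, cache$ln, blk$ln3_g)
  dX <- dX + lb$dx
  list(dX = dX,
       grads = list(W_m1 = dW_m1, b_m1 = db_m1, W_m2 = dW_m2,
                    b_m2 = db_m2, ln3_g = lb$dg, ln3_b = lb$db))
}

## Full backward pass from dlogits (B x C); returns gradients with the
## same nesting as model$params.
fga_backward <- function(model, out, dlogits) {
  cfg <- model$config; p <- model$params
  cache <- out$cache
  B <- out$B; T <- cfg$n_patches + 1L
  g <- list()
  g$head_W <- crossprod(out$features, dlogits)
  g$head_b <- colSums(dlogits)
  dfeat <- tcrossprod(dlogits, p$head_W)
  if (cfg$final_norm) {
    lb <- layer_norm_bwd(dfeat, cache$lnf, p$lnf_g)
    g$lnf_g <- lb$dg; g$lnf_b <- lb$db
    dZcls <- lb$dx
  } else dZcls <- dfeat
  dX <- matrix(0, B * T, cfg$embed_dim)
  dX[cache$emb$icls, ] <- dZcls
  g$blocks <- vector("list", cfg$depth)
  spectral_on <- cfg$use_fft || cfg$use_se
  for (l in rev(seq_len(cfg$depth))) {
    bc <- cache$blocks[[l]]
    blk <- p$blocks[[l]]
    mb <- mlp_bwd(dX, blk, cfg, bc$mlp)
    ab <- attention_bwd(mb$dX, blk, cfg, B, bc$attn, bc$attn_in)
    dX <- ab$dX
    gb <- c(ab$grads, mb$grads)
    if (spectral_on) {
      dU <- dX[cache$emb$ipatch, , drop = FALSE]
      sb <- spectral_branch_bwd(dU, blk, cfg, B, bc$sb)
      lb1 <- layer_norm_bwd(sb$dTn, bc$ln1, blk$ln1_g)
      dX[cache$emb$ipatch, ] <- dU + lb1$dx
      gb <- c(gb, sb$grads, list(ln1_g = lb1$dg, ln1_b = lb1$db))
    }
    g$blocks[[l]] <- gb[names(blk)]
  }
  dpos <- rowsum(dX, rep(seq_len(T), times = B), reorder = TRUE)
  g$pos <- dpos
  g$cls <- colSums(dX[cache$emb$icls, , drop = FALSE])
  dZp <- dX[cache$emb$ipatch, , drop = FALSE]
  g$embed_W <- crossprod(cache$Xp, dZp)
  g$embed_b <- colSums(dZp)
  g[names(p)]
}

## ---- loss ------------------------------------------------------------

#' Cross-entropy of a predicted class distribution
#'
#' `-log(probs[label])` with the probability clamped below at 1e-12 so
#' a confidently wrong prediction yields a large finite loss.  Labels
#' are 1-based class indices.
#'
#' @param probs numeric probability vector (or B x C matrix).
#' @param label integer class index in 1..C (or length-B vector).
#' @return nonnegative loss (mean over the batch for matrix input).
#' @export
cross_entropy <- function(probs, label) {
  if (is.matrix(probs)) {
    if (any(label < 1L | label > ncol(probs)))
      stopf("label out of range 1..%d", ncol(probs))
    pr <- probs[cbind(seq_len(nrow(probs)), label)]
    return(mean(-log(pmax(pr, 1e-12))))
  }
  if (label < 1L || label > length(probs))
    stopf("label out of range 1..%d", length(probs))
  -log(max(probs[label], 1e-12))
}

## Gradient of mean cross-entropy wrt logits: (softmax - onehot)/B.
ce_grad_logits <- function(probs, labels) {
  d <- probs
  d[cbind(seq_len(nrow(probs)), labels)] <-
    d[cbind(seq_len(nrow(probs)), labels)] - 1
  d / nrow(probs)
}

## ---- AdamW -----------------------------------------------------------

## Decoupled weight decay is applied to 2-D projection matrices only
## (not biases, norm parameters, tokens or the spectral filter) —
## standard transformer practice.
adamw_init <- function(params) {
  list(m = tree_map(zeros_like, params),
       v = tree_map(zeros_like, params), t = 0L)
}

decay_mask <- function(params) {
  mask_leaf <- function(name, x) {
    is.matrix(x) && !name %in% c("pos", "filt_re", "filt_im")
  }
  walk <- function(x) {
    if (is.list(x)) {
      out <- lapply(names(x) %||% seq_along(x),
                    function(nm) {
                      el <- x[[nm]]
                      if (is.list(el)) walk(el) else mask_leaf(nm, el)
                    })
      names(out) <- names(x)
      out
    } else FALSE
  }
  walk(params)
}

adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       mask = NULL) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  if (is.null(mask)) mask <- decay_mask(params)
  step_leaf <- function(p, u, dec) {
    p - lr * (u + if (isTRUE(dec)) weight_decay * p else 0)
  }
  walk <- function(p, u, d) {
    if (is.list(p)) {
      out <- mapply(walk, p, u, d, SIMPLIFY = FALSE)
      names(out) <- names(p)
      out
    } else step_leaf(p, u, d)
  }
  list(params = walk(params, upd, mask), state = state)
}
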