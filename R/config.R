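#' Encoder configuration
#'
#' Hyperparameters of the Fourier-guided attention encoder.  The defaults
#' correspond to the full-size model: 224x224 tiles cut into 16x16
#' patches (196 patch tokens), 768-dimensional embeddings, four encoder
#' blocks and twelve attention heads.
#'
#' The two flags `use_fft` and `use_se` select the ablation variant of
#' the spectral refinement stage:
#' \describe{
#'   \item{B0}{`use_fft = FALSE, use_se = FALSE` — plain pre-norm
#'     attention block, no spectral residual at all.}
#'   \item{B1}{`use_fft = TRUE, use_se = FALSE` — FFT/IFFT round trip
#'     without channel gating (an identity-valued spectral residual).}
#'   \item{B2}{`use_fft = FALSE, use_se = TRUE` — squeeze-and-excitation
#'     gate computed from spatial (not spectral) channel statistics.}
#'   \item{full}{both flags on — the complete spectral branch.}
#' }
#'
#' @param image_size input tile side in pixels; must be divisible by
#'   `patch_size`.
#' @param patch_size patch side P in pixels.
#' @param embed_dim token embedding width D; divisible by `num_heads`.
#' @param depth number of stacked encoder blocks L.
#' @param num_heads attention heads (64-dim heads at D = 768).
#' @param mlp_ratio hidden-width multiplier of the feed-forward block.
#' @param se_reduction bottleneck divisor r of the SE gate (D -> D/r -> D).
#' @param num_classes output classes C.
#' @param use_fft enable the FFT/IFFT spectral branch.
#' @param use_se enable squeeze-and-excitation channel gating.
#' @param use_spectral_filter non-canonical extension: learnable complex
#'   per-coefficient mask applied to the spectrum before gating.
#' @param final_norm layer-normalise tokens before the classification head.
#' @param drop_rate dropout probability on the MLP branch (default 0).
#' @return an object of class `fga_config`.
#' @export
fga_config <- function(image_size = 224L, patch_size = 16L,
                       embed_dim = 768L, depth = 4L, num_heads = 12L,
                       mlp_ratio = 4, se_reduction = 16L,
                       num_classes = 2L, use_fft = TRUE, use_se = TRUE,
                       use_spectral_filter = FALSE, final_norm = TRUE,
                       drop_rate = 0) {
  cfg <- list(image_size = as.integer(image_size),
              patch_size = as.integer(patch_size),
              embed_dim = as.integer(embed_dim),
              depth = as.integer(depth),
              num_heads = as.integer(num_heads),
              mlp_ratio = mlp_ratio,
              se_reduction = as.integer(se_reduction),
              num_classes = as.integer(num_classes),
              use_fft = isTRUE(use_fft), use_se = isTRUE(use_se),
              use_spectral_filter = isTRUE(use_spectral_filter),
              final_norm = isTRUE(final_norm),
              drop_rate = drop_rate)
  if (cfg$image_size %% cfg$patch_size != 0L)
    stopf("image_size (%d) must be divisible by patch_size (%d)",
          cfg$image_size, cfg$patch_size)
  if (cfg$embed_dim %% cfg$num_heads != 0L)
    stopf("embed_dim (%d) must be divisible by num_heads (%d)",
          cfg$embed_dim, cfg$num_heads)
  if (cfg$se_reduction < 1L) stopf("se_reduction must be >= 1")
  if (cfg$depth < 1L) stopf("depth must be >= 1")
  if (cfg$drop_rate < 0 || cfg$drop_rate >= 1)
    stopf("drop_rate must be in [0, 1)")
  grid <- cfg$image_size %/% cfg$patch_size
  cfg$grid_shape <- c(grid, grid)
  cfg$n_patches <- grid * grid
  cfg$se_hidden <- max(1L, cfg$embed_dim %/% cfg$se_reduction)
  class(cfg) <- "fga_config"
  cfg
}

#' Ablation variant label of a configuration
#'
#' Maps the `(use_fft, use_se)` flag pair to its variant name:
#' `"B0"`, `"B1"`, `"B2"` or `"full"`.
#'
#' @param config an [fga_config()].
#' @return a character scalar.
#' @export
variant_name <- function(config) {
  stopifnot(inherits(config, "fga_config"))
  if (config$use_fft && config$use_se) "full"
  else if (config$use_fft) "B1"
  else if (config$use_se) "B2"
  else "B0"
}

#' The four ablation variants of a base configuration
#'
#' @param base an [fga_config()]; its flags are overridden.
#' @return named list of four configs (`B0`, `B1`, `B2`, `full`).
#' @export
ablation_configs <- function(base) {
  stopifnot(inherits(base, "fga_config"))
  flags <- list(B0 = c(FALSE, FALSE), B1 = c(TRUE, FALSE),
                B2 = c(FALSE, TRUE), full = c(TRUE, TRUE))
  lapply(flags, function(f) {
    cfg <- base
    cfg$use_fft <- f[1L]; cfg$use_se <- f[2L]
    cfg
  })
}

#' @export
print.fga_config <- function(x, ...) {
  cat(sprintf(
    "<fga_config> %s | %dx%d px, P=%d (N=%d), D=%d, L=%d, heads=%d, C=%d\n",
    variant_name(x), x$image_size, x$image_size, x$patch_size,
    x$n_patches, x$embed_dim, x$depth, x$num_heads, x$num_classes))
  invisible(x)
}

#' Training configuration
#'
#' Optimisation hyperparameters.  Defaults are the published protocol:
#' 100 epochs of AdamW at learning rate 1e-4, weight decay 5e-2, batch
#' size 32, with pathology-preserving augmentation enabled.
#'
#' @param epochs training epochs.
#' @param lr AdamW learning rate.
#' @param weight_decay decoupled weight-decay coefficient (applied to
#'   projection matrices, not to biases, norm gains or tokens).
#' @param batch_size minibatch size.
#' @param seed RNG seed controlling the split, shuffling, init and
#'   augmentation draws.
#' @param augment apply online augmentation to training images.
#' @param val_fraction fraction held out (stratified) for validation.
#' @param lr_schedule `"constant"` or `"cosine"`.
#' @return an object of class `fga_train_config`.
#' @export
train_config <- function(epochs = 100L, lr = 1e-4, weight_decay = 5e-2,
                         batch_size = 32L, seed = 1L, augment = TRUE,
                         val_fraction = 0.2,
                         lr_schedule = c("constant", "cosine")) {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1,
            val_fraction > 0, val_fraction < 1, weight_decay >= 0)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), augment = isTRUE(augment),
                 val_fraction = val_fraction,
                 lr_schedule = match.arg(lr_schedule)),
            class = "fga_train_config")
}
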