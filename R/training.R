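## Training: pathology-preserving augmentation and the AdamW loop.

#' Augmentation options
#'
#' The online augmentation pipeline applies, in order: horizontal flip,
#' vertical flip, a quarter-turn rotation drawn from `rot_choices`,
#' mild colour jitter (brightness/contrast/saturation factors in
#' 0.9..1.1, hue rotation of +-0.02 turns) and a random resized crop
#' (area scale 0.8..1.0, resized back to the input size).  These
#' transforms change orientation and staining appearance but preserve
#' the diagnostic content, so the label is unchanged by contract.
#'
#' @param hflip_p,vflip_p flip probabilities.
#' @param rot_choices quarter-turn counts sampled uniformly.
#' @param jitter half-width of the brightness/contrast/saturation
#'   factor interval around 1 (0 disables jitter).
#' @param hue_shift half-width of the hue rotation in turns (0 disables).
#' @param crop_scale length-2 area-scale range of the random resized
#'   crop, or `NULL` to disable cropping.
#' @return a list of class `fga_augment_opts`.
#' @export
augment_options <- function(hflip_p = 0.5, vflip_p = 0.5,
                            rot_choices = 0:3, jitter = 0.1,
                            hue_shift = 0.02, crop_scale = c(0.8, 1)) {
  structure(list(hflip_p = hflip_p, vflip_p = vflip_p,
                 rot_choices = as.integer(rot_choices), jitter = jitter,
                 hue_shift = hue_shift, crop_scale = crop_scale),
            class = "fga_augment_opts")
}

#' Apply random pathology-preserving augmentation to one image
#'
#' Consumes the current RNG stream, so results are bitwise reproducible
#' under a fixed seed.  With all options disabled (`hflip_p = 0,
#' vflip_p = 0, rot_choices = 0, jitter = 0, hue_shift = 0,
#' crop_scale = NULL`) the output is identical to the input.
#'
#' @param img numeric array 3 x S x S in \[0, 1\].
#' @param opts an [augment_options()] list.
#' @return augmented 3 x S x S array, clipped to \[0, 1\].
#' @export
augment_image <- function(img, opts = augment_options()) {
  S <- dim(img)[2L]
  if (opts$hflip_p > 0 && stats::runif(1) < opts$hflip_p) img <- flip_h(img)
  if (opts$vflip_p > 0 && stats::runif(1) < opts$vflip_p) img <- flip_v(img)
  k <- if (length(opts$rot_choices) > 1L)
    sample(opts$rot_choices, 1L) else opts$rot_choices[1L]
  img <- rotate90(img, k)
  if (opts$jitter > 0) {
    f <- 1 + stats::runif(3L, -opts$jitter, opts$jitter)
    img <- img * f[1L]                                  # brightness
    mu <- mean(luma(img))
    img <- (img - mu) * f[2L] + mu                      # contrast
    gray <- luma(img)
    grayb <- aperm(array(gray, c(S, S, 3L)), c(3L, 1L, 2L))
    img <- grayb + (img - grayb) * f[3L]                # saturation
  }
  if (opts$hue_shift > 0)
    img <- hue_rotate(img, stats::runif(1, -opts$hue_shift, opts$hue_shift))
  if (!is.null(opts$crop_scale)) {
    s <- stats::runif(1, opts$crop_scale[1L], opts$crop_scale[2L])
    side <- max(1L, min(S, as.integer(round(S * sqrt(s)))))
    y0 <- sample.int(S - side + 1L, 1L) - 1L
    x0 <- sample.int(S - side + 1L, 1L) - 1L
    img <- bilinear_resize(
      img[, (y0 + 1L):(y0 + side), (x0 + 1L):(x0 + side), drop = FALSE],
      S, S)
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}

#' Train the encoder end-to-end with AdamW and cross-entropy
#'
#' Splits the data into stratified train/validation parts, then runs
#' minibatch AdamW at the configured hyperparameters.  Each epoch logs
#' the mean training loss, training accuracy and validation accuracy;
#' the returned model is the checkpoint with the best validation
#' accuracy (ties broken by the earlier epoch).  Fully reproducible
#' under `config$seed` on a single device.
#'
#' @param model an [fga_model()] (its initial weights are the starting
#'   point).
#' @param images numeric array 3 x S x S x n.
#' @param labels integer class labels in 1..C (length n).
#' @param config a [train_config()].
#' @param augment_opts an [augment_options()] list (used when
#'   `config$augment` is `TRUE`).
#' @return an object of class `fga_fit`: list with `model` (best
#'   checkpoint), `final_model`, `log` (one data-frame row per epoch)
#'   and `split` (the train/validation indices).
#' @export
train_fga <- function(model, images, labels, config = train_config(),
                      augment_opts = augment_options()) {
  stopifnot(inherits(model, "fga_model"),
            inherits(config, "fga_train_config"))
  cfg <- model$config
  images <- as_image_batch(images, cfg)
  n <- dim(images)[4L]
  if (n == 0L) stopf("empty dataset")
  labels <- as.integer(labels)
  stopifnot(length(labels) == n)
  if (any(labels < 1L | labels > cfg$num_classes))
    stopf("labels must lie in 1..%d", cfg$num_classes)
  sp <- stratified_split(labels, config$val_fraction, config$seed)
  if (length(unique(labels[sp$train])) < 2L)
    stopf("training split contains a single class; refusing to train")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  params <- model$params
  state <- adamw_init(params)
  mask <- decay_mask(params)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    train_acc = numeric(0), val_acc = numeric(0))
  best <- list(acc = -Inf, params = params, epoch = 0L)
  eval_acc <- function(params, idx) {
    m <- model; m$params <- params
    correct <- 0L
    for (ch in split(idx, ceiling(seq_along(idx) / config$batch_size))) {
      out <- forward_batch(m, images[, , , ch, drop = FALSE])
      correct <- correct + sum(max.col(out$probs) == labels[ch])
    }
    correct / length(idx)
  }
  for (epoch in seq_len(config$epochs)) {
    lr <- config$lr
    if (config$lr_schedule == "cosine")
      lr <- lr * 0.5 * (1 + cos(pi * (epoch - 1) / config$epochs))
    perm <- sample(sp$train)
    losses <- numeric(0)
    correct <- 0L
    for (bt in split(perm, ceiling(seq_along(perm) / config$batch_size))) {
      xb <- images[, , , bt, drop = FALSE]
      if (config$augment)
        for (j in seq_along(bt))
          xb[, , , j] <- augment_image(xb[, , , j], augment_opts)
      m <- model; m$params <- params
      out <- forward_batch(m, xb, mode = "train")
      yb <- labels[bt]
      losses <- c(losses, cross_entropy(out$probs, yb))
      correct <- correct + sum(max.col(out$probs) == yb)
      grads <- fga_backward(m, out, ce_grad_logits(out$probs, yb))
      st <- adamw_step(params, grads, state, lr, config$weight_decay,
                       mask = mask)
      params <- st$params; state <- st$state
    }
    vacc <- eval_acc(params, sp$test)
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = mean(losses),
                                 train_acc = correct / length(perm),
                                 val_acc = vacc))
    if (vacc > best$acc) best <- list(acc = vacc, params = params,
                                      epoch = epoch)
  }
  best_model <- model; best_model$params <- best$params
  final_model <- model; final_model$params <- params
  structure(list(model = best_model, final_model = final_model,
                 log = log, split = sp, best_epoch = best$epoch),
            class = "fga_fit")
}

#' @export
print.fga_fit <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf(
    "<fga_fit> %d epochs; best val acc %.3f (epoch %d); final train loss %.4f\n",
    n, max(x$log$val_acc), x$best_epoch, x$log$train_loss[n]))
  invisible(x)
}
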