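## Ablation grid: train the B0/B1/B2/full variants on identical data
## and seeds, export features, and score them with the downstream
## protocol.

## Feature extraction in evaluation mode, chunked to bound memory.
extract_features_batched <- function(model, images, chunk = 32L) {
  n <- dim(images)[4L]
  out <- matrix(0, n, model$config$embed_dim)
  for (ch in split(seq_len(n), ceiling(seq_len(n) / chunk)))
    out[ch, ] <- fga_extract(model, images[, , , ch, drop = FALSE])
  out
}

#' Train and score the four spectral-block ablation variants
#'
#' For every seed and every variant (B0, B1, B2, full — see
#' [ablation_configs()]): initialise a model, train it on the dataset
#' with identical splits and hyperparameters, export the class-token
#' features of all images from the best-validation checkpoint, and
#' score them with the chosen downstream classifiers.
#'
#' @param images numeric array 3 x S x S x n.
#' @param labels integer labels in 1..C.
#' @param base_config an [fga_config()] whose flags are overridden per
#'   variant.
#' @param train_cfg a [train_config()]; its `seed` is replaced by each
#'   element of `seeds`.
#' @param seeds integer vector of replicate seeds.
#' @param classifiers subset of [classifier_protocol()] names to score.
#' @param verbose log progress to stderr.
#' @return data.frame with one row per (seed, variant, classifier):
#'   `variant`, `seed`, `classifier`, `accuracy` (percent) and the
#'   positive-class metrics.
#' @export
ablation_study <- function(images, labels, base_config, train_cfg,
                           seeds = 1L, classifiers = "ann",
                           verbose = FALSE) {
  protocol <- classifier_protocol()[classifiers]
  if (any(vapply(protocol, is.null, logical(1L))))
    stopf("unknown classifier in: %s", paste(classifiers, collapse = ", "))
  cfgs <- ablation_configs(base_config)
  rows <- list()
  for (seed in seeds) {
    for (vn in names(cfgs)) {
      tc <- train_cfg
      tc$seed <- as.integer(seed)
      model <- fga_model(cfgs[[vn]], seed = seed)
      if (verbose) log_msg("training %s (seed %d)", vn, seed)
      fit <- train_fga(model, images, labels, tc)
      feats <- extract_features_batched(fit$model, images)
      reports <- fit_and_evaluate(feats, labels, protocol,
                                  split_seed = seed)
      for (cn in names(reports)) {
        r <- reports[[cn]]
        rows[[length(rows) + 1L]] <- data.frame(
          variant = vn, seed = seed, classifier = cn,
          accuracy = r$accuracy,
          precision = r$per_class$precision[2L],
          recall = r$per_class$recall[2L],
          specificity = r$per_class$specificity[2L],
          f1 = r$per_class$f1[2L])
      }
      if (verbose)
        log_msg("%s seed %d: downstream %s", vn, seed,
                paste(sprintf("%s %.1f%%", names(reports),
                              vapply(reports, `[[`, 0, "accuracy")),
                      collapse = ", "))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
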