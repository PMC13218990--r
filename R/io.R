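## Checkpoints and feature tables.

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized container holding all weights
#' plus the model configuration.  Loading validates that every weight
#' tensor matches the shape the stored configuration implies, so a
#' corrupted or mismatched file fails loudly.
#'
#' @param model an [fga_model()].
#' @param path file path (conventionally `.rds`).
#' @param extra optional named list stored alongside (e.g. a train log).
#' @return `save_checkpoint`: the path, invisibly; `load_checkpoint`:
#'   the model (extras in `attr(model, "extra")`).
#' @export
save_checkpoint <- function(model, path, extra = NULL) {
  stopifnot(inherits(model, "fga_model"))
  saveRDS(list(config = model$config, params = model$params,
               extra = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!all(c("config", "params") %in% names(obj)))
    stopf("'%s' is not a model checkpoint", path)
  cfg <- obj$config
  ref <- fga_model(cfg, seed = 1L)$params
  chk <- function(a, b, where) {
    if (is.list(a)) {
      if (!setequal(names(a), names(b)))
        stopf("checkpoint weights at '%s' do not match the stored config",
              where)
      for (nm in names(a)) chk(a[[nm]], b[[nm]], paste(where, nm, sep = "/"))
    } else if (!identical(dim(a) %||% length(a), dim(b) %||% length(b))) {
      stopf("weight shape mismatch at '%s'", where)
    }
  }
  chk(ref, obj$params, "params")
  model <- structure(list(config = cfg, params = obj$params),
                     class = "fga_model")
  attr(model, "extra") <- obj$extra
  model
}

#' Write / read an exported feature table
#'
#' CSV with one row per image: `image_id`, `label` (may be `NA`), then
#' the D feature columns `f1..fD`.  The same contract is used for
#' encoder features and handcrafted descriptors, so the downstream
#' protocol consumes both interchangeably.
#'
#' @param features numeric n x D matrix.
#' @param path output CSV path.
#' @param ids image identifiers (default `img_1..n`).
#' @param labels optional labels (integer codes or class names).
#' @return `write_features`: the path, invisibly; `read_features`: a
#'   list with `features`, `ids`, `labels`.
#' @export
write_features <- function(features, path, ids = NULL, labels = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  df <- data.frame(image_id = ids %||% paste0("img_", seq_len(n)),
                   label = if (is.null(labels)) NA else labels)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  utils::write.csv(cbind(df, features), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fcols <- grep("^f[0-9]+$", colnames(df))
  list(features = as.matrix(df[, fcols, drop = FALSE]),
       ids = df$image_id, labels = df$label)
}
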