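## The unified transferability protocol: fit seven fixed shallow
## classifiers on exported feature vectors and report accuracy plus
## class-wise precision / recall / specificity / F1 (all in %), the
## schema of the published benchmark tables.

#' The seven-classifier downstream protocol
#'
#' Returns the fixed classifier roster used to score feature
#' representations: logistic regression, kNN (k = 9), Gaussian naive
#' Bayes, random forest (10 trees), linear-kernel SVM, RBF-kernel SVM
#' and a feed-forward ANN with two hidden layers (100 + 100 units).
#'
#' @return named list of seven classifier specs (`name`, `params`).
#' @export
classifier_protocol <- function() {
  list(
    logistic_regression = list(name = "logistic_regression", params = list()),
    knn = list(name = "knn", params = list(k = 9L)),
    naive_bayes = list(name = "naive_bayes", params = list()),
    random_forest = list(name = "random_forest", params = list(n_trees = 10L)),
    svm_linear = list(name = "svm_linear", params = list(C = 1)),
    svm_rbf = list(name = "svm_rbf", params = list(C = 1)),
    ann = list(name = "ann",
               params = list(hidden = c(100L, 100L), max_iter = 500L)))
}

#' Class-wise metrics from a confusion matrix
#'
#' Rows of `cm` are true classes, columns predicted classes.  For the
#' chosen positive class: precision = TP/(TP+FP), recall = TP/(TP+FN),
#' specificity = TN/(TN+FP), F1 = harmonic mean of precision and
#' recall.  Ratios with a zero denominator are reported as `NA`
#' (the "-" cells of a degenerate classifier).  Values are percentages.
#'
#' @param cm square matrix of nonnegative integer counts.
#' @param positive_class row/column index (or name) of the positive class.
#' @return named numeric vector
#'   `c(precision, recall, specificity, f1)` in percent.
#' @export
confusion_metrics <- function(cm, positive_class) {
  cm <- as.matrix(cm)
  if (length(cm) == 0L || nrow(cm) != ncol(cm))
    stopf("confusion matrix must be square and non-empty")
  if (is.character(positive_class))
    positive_class <- match(positive_class, rownames(cm))
  i <- positive_class
  tp <- cm[i, i]
  fp <- sum(cm[-i, i])
  fn <- sum(cm[i, -i])
  tn <- sum(cm[-i, -i])
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  prec <- ratio(tp, tp + fp)
  rec <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  c(precision = prec, recall = rec, specificity = spec, f1 = f1)
}

#' Build an evaluation report from predictions
#'
#' @param truth,pred integer class labels (1..C).
#' @param n_classes number of classes C.
#' @param class_names optional class names for the report.
#' @return an object of class `fga_eval_report`: list with `accuracy`
#'   (percent), `per_class` (one metric row per class) and `cm`.
#' @export
eval_report <- function(truth, pred, n_classes = max(truth),
                        class_names = NULL) {
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth))
    cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  if (is.null(class_names)) class_names <- paste0("class", seq_len(n_classes))
  dimnames(cm) <- list(truth = class_names, pred = class_names)
  per <- t(sapply(seq_len(n_classes), function(i) confusion_metrics(cm, i)))
  rownames(per) <- class_names
  structure(list(accuracy = 100 * sum(diag(cm)) / sum(cm),
                 per_class = as.data.frame(per), cm = cm),
            class = "fga_eval_report")
}

#' @export
print.fga_eval_report <- function(x, ...) {
  cat(sprintf("<fga_eval_report> accuracy %.2f%% (n = %d)\n",
              x$accuracy, sum(x$cm)))
  print(round(x$per_class, 2))
  invisible(x)
}

#' Fit and score the downstream protocol on a feature matrix
#'
#' Splits the samples with a stratified 80/20 split, standardises the
#' features with training-split statistics (columns with zero training
#' variance are left unscaled, with a warning if all are degenerate),
#' fits every classifier of the protocol on the same split and scores
#' it on the held-out part.
#'
#' @param features numeric n x D matrix.
#' @param labels integer class labels in 1..C.
#' @param protocol classifier roster, default [classifier_protocol()].
#' @param split_seed seed for the stratified split and all classifier
#'   RNG.
#' @param test_fraction held-out fraction (default 0.2).
#' @return named list of [eval_report()] objects, one per classifier.
#' @export
fit_and_evaluate <- function(features, labels,
                             protocol = classifier_protocol(),
                             split_seed = 1L, test_fraction = 0.2) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  n <- nrow(features)
  if (n < 20L) stopf("need at least 20 samples, got %d", n)
  sp <- stratified_split(labels, test_fraction, split_seed)
  if (length(unique(labels[sp$train])) < 2L ||
      length(unique(labels[sp$test])) < 2L)
    stopf("both classes must be present in train and test splits")
  mu <- colMeans(features[sp$train, , drop = FALSE])
  sd <- apply(features[sp$train, , drop = FALSE], 2L, stats::sd)
  keep <- is.finite(sd) & sd > 0
  if (!any(keep)) {
    warning("all feature columns have zero training variance; skipping standardisation")
    Xs <- features
  } else {
    sd[!keep] <- 1
    Xs <- sweep(sweep(features, 2L, mu), 2L, sd, "/")
  }
  nc <- max(labels)
  Xtr <- Xs[sp$train, , drop = FALSE]
  Xte <- Xs[sp$test, , drop = FALSE]
  ytr <- labels[sp$train]; yte <- labels[sp$test]
  out <- lapply(protocol, function(spec) {
    fit <- shallow_fit(spec$name, Xtr, ytr, spec$params, seed = split_seed)
    eval_report(yte, shallow_predict(fit, Xte), n_classes = nc)
  })
  names(out) <- names(protocol)
  out
}

#' Flatten evaluation reports to a benchmark-style table
#'
#' One row per classifier with accuracy and the class-wise
#' precision/recall/specificity/F1 columns for each class.
#'
#' @param reports named list of [eval_report()] objects.
#' @param class_names optional class names used in column headers.
#' @return a data.frame.
#' @export
metrics_table <- function(reports, class_names = NULL) {
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    cn <- class_names %||% rownames(r$per_class)
    row <- data.frame(classifier = nm, accuracy = r$accuracy)
    for (i in seq_len(nrow(r$per_class))) {
      v <- r$per_class[i, ]
      names(v) <- paste(cn[i], names(v), sep = "_")
      row <- cbind(row, v)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
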