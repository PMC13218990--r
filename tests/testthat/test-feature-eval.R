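# Confusion metrics and the seven-classifier downstream protocol.

test_that("confusion metrics match direct arithmetic", {
  cm <- rbind(c(9, 1), c(2, 8))
  m <- confusion_metrics(cm, 1)
  expect_equal(unname(round(m, 2)),
               c(81.82, 90.00, 80.00, 85.71))
  # all-correct classifier: every metric 100
  expect_equal(unname(confusion_metrics(diag(c(5, 7)), 2)),
               c(100, 100, 100, 100))
  expect_error(confusion_metrics(matrix(0, 0, 0), 1), "square")
})

test_that("degenerate one-class predictor mirrors the benchmark's '-' rows", {
  # balanced binary set, everything predicted class 2 ("malignant")
  truth <- rep(1:2, each = 20)
  pred <- rep(2L, 40)
  r <- eval_report(truth, pred, class_names = c("benign", "malignant"))
  expect_equal(r$per_class["malignant", "recall"], 100)
  expect_equal(r$per_class["malignant", "specificity"], 0)
  expect_equal(r$per_class["benign", "recall"], 0)
  expect_true(is.na(r$per_class["benign", "precision"]))  # the "-" cell
  expect_equal(r$accuracy, 50)
})

test_that("binary duality: specificity of one class is recall of the other", {
  set.seed(31)
  for (i in 1:20) {
    truth <- sample(1:2, 60, replace = TRUE)
    pred <- sample(1:2, 60, replace = TRUE)
    r <- eval_report(truth, pred, n_classes = 2L)
    expect_equal(r$per_class$specificity[1], r$per_class$recall[2])
    expect_equal(r$per_class$specificity[2], r$per_class$recall[1])
    expect_equal(r$accuracy, 100 * sum(diag(r$cm)) / sum(r$cm))
    expect_equal(sum(r$cm), 60)
  }
})

sep_features <- function(n, gap, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(1:2, each = n / 2)
    x <- matrix(rnorm(n * 2), n, 2)
    x[y == 2, 1] <- x[y == 2, 1] + gap
    list(x = x, y = y)
  })
}

test_that("well-separated clusters are solved by every protocol member", {
  fx <- sep_features(200, gap = 10)
  reports <- fit_and_evaluate(fx$x, fx$y, split_seed = 7)
  expect_named(reports, names(classifier_protocol()))
  expect_length(reports, 7L)
  for (nm in names(reports))
    expect_gte(reports[[nm]]$accuracy, 95)
})

test_that("label-independent noise scores at chance level", {
  fx <- sep_features(400, gap = 0, seed = 1)
  reports <- fit_and_evaluate(fx$x, fx$y, split_seed = 1)
  for (nm in names(reports)) {
    expect_gte(reports[[nm]]$accuracy, 40)
    expect_lte(reports[[nm]]$accuracy, 60)
  }
})

test_that("reports are deterministic under the split seed", {
  fx <- sep_features(100, gap = 2, seed = 3)
  proto <- classifier_protocol()[c("random_forest", "ann", "svm_rbf")]
  r1 <- fit_and_evaluate(fx$x, fx$y, proto, split_seed = 9)
  r2 <- fit_and_evaluate(fx$x, fx$y, proto, split_seed = 9)
  expect_identical(r1, r2)
})

test_that("degenerate features trigger the standardisation warning", {
  x <- matrix(1, 40, 3)
  y <- rep(1:2, 20)
  expect_warning(fit_and_evaluate(x, y, classifier_protocol()["naive_bayes"],
                                  split_seed = 1),
                 "zero training variance")
  expect_error(fit_and_evaluate(x[1:10, ], y[1:10]), "at least 20")
})

test_that("metrics_table flattens one row per classifier", {
  fx <- sep_features(60, gap = 3, seed = 4)
  proto <- classifier_protocol()[c("knn", "naive_bayes")]
  tab <- metrics_table(fit_and_evaluate(fx$x, fx$y, proto, split_seed = 2))
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("classifier", "accuracy") %in% colnames(tab)))
})
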