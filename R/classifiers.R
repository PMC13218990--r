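## The seven downstream shallow classifiers of the transferability
## protocol.  Only logistic regression rides on stats::glm; the rest
## (kNN, Gaussian naive Bayes, random forest, both SVMs, the small ANN)
## are self-contained because no machine-learning package is assumed
## beyond base R.  All fits are deterministic given `seed`.
##
## Internal API: shallow_fit(name, X, y, params, seed) -> fit object;
## shallow_predict(fit, X) -> integer labels (1..C).

shallow_fit <- function(name, X, y, params = list(), seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  nc <- max(y)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fit <- switch(
    name,
    logistic_regression = fit_logistic(X, y, nc),
    knn = list(X = X, y = y, k = params$k %||% 9L),
    naive_bayes = fit_gnb(X, y, nc),
    random_forest = fit_rforest(X, y, nc,
                                n_trees = params$n_trees %||% 10L,
                                max_depth = params$max_depth %||% 12L),
    svm_linear = fit_svm_linear(X, y, nc, C = params$C %||% 1),
    svm_rbf = fit_svm_rbf(X, y, nc, C = params$C %||% 1,
                          gamma = params$gamma),
    ann = fit_ann(X, y, nc,
                  hidden = params$hidden %||% c(100L, 100L),
                  max_iter = params$max_iter %||% 500L,
                  lr = params$lr %||% 1e-3),
    stopf("unknown classifier '%s'", name))
  structure(c(fit, list(name = name, n_classes = nc)),
            class = "fga_shallow")
}

shallow_predict <- function(fit, X) {
  X <- as.matrix(X)
  switch(
    fit$name,
    logistic_regression = predict_logistic(fit, X),
    knn = predict_knn(fit, X),
    naive_bayes = predict_gnb(fit, X),
    random_forest = predict_rforest(fit, X),
    svm_linear = predict_svm_linear(fit, X),
    svm_rbf = predict_svm_rbf(fit, X),
    ann = predict_ann(fit, X))
}

## ---- logistic regression (binary; stats::glm) ------------------------

fit_logistic <- function(X, y, nc) {
  if (nc != 2L) stopf("logistic regression head supports 2 classes")
  df <- data.frame(y = y - 1L, X)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial(),
               control = list(maxit = 50)))
  list(coef = stats::coef(fit))
}

predict_logistic <- function(fit, X) {
  eta <- cbind(1, X) %*% ifelse(is.na(fit$coef), 0, fit$coef)
  as.integer(eta > 0) + 1L
}

## ---- k-nearest neighbours (k = 9) ------------------------------------

predict_knn <- function(fit, X) {
  # squared Euclidean distances test x train, fully vectorised
  d2 <- outer(rowSums(X^2), rowSums(fit$X^2), "+") - 2 * tcrossprod(X, fit$X)
  k <- min(fit$k, nrow(fit$X))
  apply(d2, 1L, function(row) {
    nb <- order(row)[seq_len(k)]
    votes <- tabulate(fit$y[nb], fit$n_classes)
    win <- which(votes == max(votes))
    if (length(win) == 1L) win else fit$y[nb[fit$y[nb] %in% win][1L]]
  })
}

## ---- Gaussian naive Bayes --------------------------------------------

fit_gnb <- function(X, y, nc) {
  mu <- rowsum(X, y) / as.vector(table(y))
  v <- rowsum(X^2, y) / as.vector(table(y)) - mu^2
  list(mu = mu, var = pmax(v, 1e-9),
       logprior = log(as.vector(table(y)) / length(y)))
}

predict_gnb <- function(fit, X) {
  ll <- sapply(seq_len(nrow(fit$mu)), function(cl) {
    m <- fit$mu[cl, ]; v <- fit$var[cl, ]
    rowSums(-0.5 * (sweep(X, 2L, m)^2) / rep(v, each = nrow(X)) -
              0.5 * rep(log(2 * pi * v), each = nrow(X))) +
      fit$logprior[cl]
  })
  max.col(matrix(ll, nrow(X)))
}

## ---- random forest (10 CART trees, gini, per-node feature draw) ------

tree_grow <- function(X, y, nc, idx, depth, max_depth, mtry) {
  counts <- tabulate(y[idx], nc)
  if (depth >= max_depth || length(idx) < 2L || sum(counts > 0L) == 1L)
    return(list(leaf = TRUE, pred = which.max(counts)))
  feats <- sample.int(ncol(X), mtry)
  best <- NULL; best_gain <- 1e-12
  n <- length(idx)
  gini <- function(cnt) 1 - sum((cnt / max(sum(cnt), 1L))^2)
  g0 <- gini(counts)
  for (f in feats) {
    v <- X[idx, f]
    u <- sort(unique(v))
    if (length(u) < 2L) next
    if (length(u) > 16L)
      u <- unique(stats::quantile(v, probs = seq(0.05, 0.95, length.out = 15),
                                  names = FALSE, type = 1L))
    thr <- (u[-length(u)] + u[-1L]) / 2
    for (t in thr) {
      left <- v <= t
      nl <- sum(left)
      if (nl == 0L || nl == n) next
      cl <- tabulate(y[idx[left]], nc)
      cr <- counts - cl
      gain <- g0 - (nl / n) * gini(cl) - ((n - nl) / n) * gini(cr)
      if (gain > best_gain) { best_gain <- gain; best <- list(f = f, t = t) }
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, pred = which.max(counts)))
  left <- X[idx, best$f] <= best$t
  list(leaf = FALSE, f = best$f, t = best$t,
       l = tree_grow(X, y, nc, idx[left], depth + 1L, max_depth, mtry),
       r = tree_grow(X, y, nc, idx[!left], depth + 1L, max_depth, mtry))
}

tree_predict1 <- function(node, x) {
  while (!node$leaf) node <- if (x[node$f] <= node$t) node$l else node$r
  node$pred
}

fit_rforest <- function(X, y, nc, n_trees, max_depth) {
  mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- lapply(seq_len(n_trees), function(i) {
    boot <- sample.int(nrow(X), nrow(X), replace = TRUE)
    tree_grow(X, y, nc, boot, 0L, max_depth, mtry)
  })
  list(trees = trees)
}

predict_rforest <- function(fit, X) {
  votes <- sapply(fit$trees, function(tr)
    apply(X, 1L, function(x) tree_predict1(tr, x)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  apply(votes, 1L, function(v) which.max(tabulate(v, fit$n_classes)))
}

## ---- linear SVM (dual coordinate descent, L1 hinge, C = 1) -----------
## Bias handled by an augmented constant feature (LIBLINEAR-style).

fit_svm_linear <- function(X, y, nc, C = 1, passes = 100L) {
  if (nc != 2L) stopf("SVM heads support 2 classes")
  Xa <- cbind(X, 1)
  yy <- ifelse(y == 2L, 1, -1)
  n <- nrow(Xa)
  alpha <- numeric(n)
  w <- numeric(ncol(Xa))
  qii <- rowSums(Xa^2)
  for (p in seq_len(passes)) {
    changed <- 0
    for (i in sample.int(n)) {
      gi <- yy[i] * sum(w * Xa[i, ]) - 1
      ai <- alpha[i]
      anew <- min(max(ai - gi / max(qii[i], 1e-12), 0), C)
      if (abs(anew - ai) > 1e-12) {
        w <- w + (anew - ai) * yy[i] * Xa[i, ]
        alpha[i] <- anew
        changed <- changed + abs(anew - ai)
      }
    }
    if (changed < 1e-6) break
  }
  list(w = w)
}

predict_svm_linear <- function(fit, X) {
  as.integer(cbind(X, 1) %*% fit$w > 0) + 1L
}

## ---- RBF-kernel SVM (kernel dual coordinate descent, C = 1) ----------
## gamma defaults to 1 / (p * var(X)) ("scale" convention).  The dual is
## solved without an intercept term (the equality constraint is dropped;
## standard for RBF kernels, where the feature map is universal).

rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

fit_svm_rbf <- function(X, y, nc, C = 1, gamma = NULL, passes = 100L) {
  if (nc != 2L) stopf("SVM heads support 2 classes")
  if (is.null(gamma)) {
    v <- stats::var(as.vector(X))
    gamma <- 1 / (ncol(X) * max(v, 1e-12))
  }
  yy <- ifelse(y == 2L, 1, -1)
  K <- rbf_kernel(X, X, gamma)
  n <- nrow(X)
  alpha <- numeric(n)
  f <- numeric(n)                       # f_i = sum_j alpha_j y_j K_ij
  for (p in seq_len(passes)) {
    changed <- 0
    for (i in sample.int(n)) {
      gi <- yy[i] * f[i] - 1
      ai <- alpha[i]
      anew <- min(max(ai - gi / K[i, i], 0), C)
      if (abs(anew - ai) > 1e-12) {
        f <- f + (anew - ai) * yy[i] * K[, i]
        alpha[i] <- anew
        changed <- changed + abs(anew - ai)
      }
    }
    if (changed < 1e-6) break
  }
  sv <- alpha > 1e-8
  list(Xsv = X[sv, , drop = FALSE], coef = (alpha * yy)[sv], gamma = gamma)
}

predict_svm_rbf <- function(fit, X) {
  if (nrow(fit$Xsv) == 0L) return(rep(1L, nrow(X)))
  dec <- rbf_kernel(X, fit$Xsv, fit$gamma) %*% fit$coef
  as.integer(dec > 0) + 1L
}

## ---- two-hidden-layer ANN (100 + 100 ReLU units, Adam) ---------------

fit_ann <- function(X, y, nc, hidden = c(100L, 100L), max_iter = 500L,
                    lr = 1e-3, l2 = 1e-4) {
  sizes <- c(ncol(X), hidden, nc)
  W <- lapply(seq_len(length(sizes) - 1L), function(i)
    matrix(stats::rnorm(sizes[i] * sizes[i + 1L],
                        sd = sqrt(2 / sizes[i])), sizes[i]))
  b <- lapply(sizes[-1L], numeric)
  Y <- diag(nc)[y, , drop = FALSE]
  mW <- lapply(W, zeros_like); vW <- lapply(W, zeros_like)
  mb <- lapply(b, zeros_like); vb <- lapply(b, zeros_like)
  nl <- length(W)
  for (it in seq_len(max_iter)) {
    acts <- list(X)
    for (i in seq_len(nl)) {
      z <- acts[[i]] %*% W[[i]] + rep(b[[i]], each = nrow(X))
      acts[[i + 1L]] <- if (i < nl) pmax(z, 0) else softmax_rows(z)
    }
    delta <- (acts[[nl + 1L]] - Y) / nrow(X)
    for (i in rev(seq_len(nl))) {
      gW <- crossprod(acts[[i]], delta) + l2 * W[[i]]
      gb <- colSums(delta)
      if (i > 1L)
        delta <- tcrossprod(delta, W[[i]]) * (acts[[i]] > 0)
      mW[[i]] <- 0.9 * mW[[i]] + 0.1 * gW
      vW[[i]] <- 0.999 * vW[[i]] + 0.001 * gW^2
      mb[[i]] <- 0.9 * mb[[i]] + 0.1 * gb
      vb[[i]] <- 0.999 * vb[[i]] + 0.001 * gb^2
      bc1 <- 1 - 0.9^it; bc2 <- 1 - 0.999^it
      W[[i]] <- W[[i]] - lr * (mW[[i]] / bc1) / (sqrt(vW[[i]] / bc2) + 1e-8)
      b[[i]] <- b[[i]] - lr * (mb[[i]] / bc1) / (sqrt(vb[[i]] / bc2) + 1e-8)
    }
  }
  list(W = W, b = b)
}

predict_ann <- function(fit, X) {
  a <- X
  nl <- length(fit$W)
  for (i in seq_len(nl)) {
    z <- a %*% fit$W[[i]] + rep(fit$b[[i]], each = nrow(X))
    a <- if (i < nl) pmax(z, 0) else z
  }
  max.col(a)
}
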