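# Loss, augmentation and the optimisation loop.

test_that("cross-entropy matches direct evaluation", {
  expect_equal(cross_entropy(c(0.5, 0.5), 1L), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy(c(0, 1), 2L), 0, tolerance = 1e-12)
  expect_equal(cross_entropy(c(0.9, 0.1), 1L), -log(0.9), tolerance = 1e-12)
  expect_error(cross_entropy(c(0.5, 0.5), 3L), "out of range")
  # clamped at 1e-12: a zero-probability true class stays finite
  expect_true(is.finite(cross_entropy(c(0, 1), 1L)))
  # matrix form averages over the batch
  pm <- rbind(c(0.5, 0.5), c(0.9, 0.1))
  expect_equal(cross_entropy(pm, c(1L, 1L)),
               mean(c(log(2), -log(0.9))), tolerance = 1e-12)
})

test_that("disabled augmentation is the identity; seeds reproduce bitwise", {
  img <- rand_images(1, 16, seed = 21)[, , , 1]
  off <- augment_options(hflip_p = 0, vflip_p = 0, rot_choices = 0L,
                         jitter = 0, hue_shift = 0, crop_scale = NULL)
  expect_identical(augment_image(img, off), img)
  a1 <- withr::with_seed(3, augment_image(img))
  a2 <- withr::with_seed(3, augment_image(img))
  expect_identical(a1, a2)
  expect_equal(dim(a1), dim(img))
  expect_true(all(a1 >= 0 & a1 <= 1))
})

test_that("quarter rotations compose to the identity", {
  img <- rand_images(1, 16, seed = 22)[, , , 1]
  rot_only <- augment_options(hflip_p = 0, vflip_p = 0, rot_choices = 1L,
                              jitter = 0, hue_shift = 0, crop_scale = NULL)
  out <- img
  for (i in 1:4) out <- augment_image(out, rot_only)
  expect_equal(out, img, tolerance = 1e-12)
  # and rotate90 itself forms the cyclic group of order 4
  expect_identical(rotate90(rotate90(img, 2), 2), img)
})

micro_train <- function(seed = 1, epochs = 3L, n = 24L) {
  ds <- small_synth()
  idx <- c(seq_len(n / 2), 30L + seq_len(n / 2))
  cfg <- tiny_config(image_size = 32L, depth = 1L)
  tc <- train_config(epochs = epochs, batch_size = 8L, seed = seed,
                     augment = FALSE, lr = 1e-3)
  train_fga(fga_model(cfg, seed = seed),
            ds$images[, , , idx, drop = FALSE], ds$labels[idx], tc)
}

test_that("training logs one finite record per epoch and is reproducible", {
  f1 <- micro_train()
  expect_equal(f1$log$epoch, 1:3)
  expect_true(all(is.finite(f1$log$train_loss)))
  expect_true(all(f1$log$train_loss >= 0))
  f2 <- micro_train()
  expect_identical(f1$log, f2$log)
  expect_equal(f1$model$params, f2$model$params)
})

test_that("best-validation checkpoint selection breaks ties earlier", {
  f <- micro_train(seed = 2)
  expect_equal(f$best_epoch,
               which(f$log$val_acc == max(f$log$val_acc))[1L])
})

test_that("degenerate datasets are refused", {
  ds <- small_synth()
  cfg <- tiny_config(image_size = 32L)
  model <- fga_model(cfg, seed = 1)
  tc <- train_config(epochs = 1L, seed = 1)
  one_class <- ds$images[, , , 1:10, drop = FALSE]
  expect_error(train_fga(model, one_class, rep(1L, 10), tc),
               "single class")
  expect_error(train_fga(model, ds$images[, , , 1:10, drop = FALSE],
                         rep(3L, 10), tc), "labels")
})

test_that("uniform head gives loss ln C at the first step", {
  ds <- small_synth()
  cfg <- tiny_config(image_size = 32L)
  model <- fga_model(cfg, seed = 5)
  model$params$head_W[] <- 0
  model$params$head_b[] <- 0
  out <- fgar:::forward_batch(model, ds$images[, , , 1:8, drop = FALSE])
  expect_equal(cross_entropy(out$probs, ds$labels[1:8]), log(2),
               tolerance = 1e-9)
})
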