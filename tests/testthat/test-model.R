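# Encoder: tokenization, block operations, ablation reductions,
# forward/extract contracts.

test_that("patch counts follow (S/P)^2 across geometries", {
  cases <- list(list(S = 224L, P = 16L, N = 196L, grid = c(14L, 14L)),
                list(S = 16L, P = 16L, N = 1L, grid = c(1L, 1L)),
                list(S = 64L, P = 8L, N = 64L, grid = c(8L, 8L)))
  for (cs in cases) {
    cfg <- tiny_config(image_size = cs$S, patch_size = cs$P)
    model <- fga_model(cfg, seed = 1)
    img <- rand_images(1, cs$S)[, , , 1]
    tok <- patch_embed(img, model)
    expect_equal(nrow(tok$tokens), cs$N + 1L)
    expect_equal(ncol(tok$tokens), cfg$embed_dim)
    expect_equal(tok$grid_shape, cs$grid)
  }
})

test_that("patch_embed rejects wrongly sized input, naming the expectation", {
  model <- fga_model(tiny_config(), seed = 1)
  expect_error(patch_embed(rand_images(1, 24)[, , , 1], model),
               "24 x 24.*16 x 16")
  bad <- rand_images(1, 16)[, , , 1]
  bad[1, 1, 1] <- Inf
  expect_error(patch_embed(bad, model), "non-finite")
})

test_that("class token and positional embedding enter row 0 as specified", {
  cfg <- tiny_config()
  model <- fga_model(cfg, seed = 3)
  img <- rand_images(1, 16, seed = 5)[, , , 1]
  tok <- patch_embed(img, model)
  expect_equal(tok$tokens[1, ],
               model$params$cls + model$params$pos[1, ])
})

# --- ablation reductions against the gating-commutation oracle --------

far_tokens <- function(seed = 7) {
  cfg <- tiny_config(image_size = 32L, embed_dim = 8L, num_heads = 2L,
                     se_reduction = 2L)
  model <- fga_model(cfg, seed = seed)
  img <- rand_images(1, 32, seed = seed)[, , , 1]
  list(cfg = cfg, model = model, tok = patch_embed(img, model))
}

test_that("B1 spectral residual reduces to T + LN(T)", {
  fx <- far_tokens()
  blk <- fx$model$params$blocks[[1]]
  cfg_b1 <- fx$cfg; cfg_b1$use_fft <- TRUE; cfg_b1$use_se <- FALSE
  cfg_b0 <- fx$cfg; cfg_b0$use_fft <- FALSE; cfg_b0$use_se <- FALSE
  out <- far_refine(fx$tok, blk, cfg_b1)
  # oracle: add LN(T) by hand, then run the spectral-free block
  Tm <- fx$tok$tokens[-1, ]
  oracle_in <- fx$tok$tokens
  oracle_in[-1, ] <- Tm + ref_layer_norm(Tm, blk$ln1_g, blk$ln1_b)
  oracle <- far_refine(oracle_in, blk, cfg_b0)
  expect_rel_equal(out, oracle, 1e-4)
})

test_that("full spectral residual reduces to T + g (x) LN(T)", {
  fx <- far_tokens(seed = 8)
  blk <- fx$model$params$blocks[[1]]
  cfg_b0 <- fx$cfg; cfg_b0$use_fft <- FALSE; cfg_b0$use_se <- FALSE
  out <- far_refine(fx$tok, blk, fx$cfg)    # full variant
  Tm <- fx$tok$tokens[-1, ]
  Tn <- ref_layer_norm(Tm, blk$ln1_g, blk$ln1_b)
  g <- se_gate(fft2(to_patch_grid(Tn, fx$tok$grid_shape)),
               list(W1 = blk$se_W1, b1 = blk$se_b1,
                    W2 = blk$se_W2, b2 = blk$se_b2))
  oracle_in <- fx$tok$tokens
  oracle_in[-1, ] <- Tm + Tn * rep(g, each = nrow(Tn))
  oracle <- far_refine(oracle_in, blk, cfg_b0)
  expect_rel_equal(out, oracle, 1e-4)
})

test_that("B0 has no spectral residual: attention-only block", {
  fx <- far_tokens(seed = 9)
  blk <- fx$model$params$blocks[[1]]
  cfg_b0 <- fx$cfg; cfg_b0$use_fft <- FALSE; cfg_b0$use_se <- FALSE
  out <- far_refine(fx$tok, blk, cfg_b0)
  # residual structure: out - tokens equals the attention branch, which
  # must be invariant to adding the spectral residual by hand first
  expect_equal(dim(out), dim(fx$tok$tokens))
  # cross-check against full variant: they must differ
  expect_false(isTRUE(all.equal(out, far_refine(fx$tok, blk, fx$cfg))))
})

test_that("spectral branch is sensitive to patch arrangement", {
  fx <- far_tokens(seed = 10)
  blk <- fx$model$params$blocks[[1]]
  perm <- withr::with_seed(10,
    c(1L, 1L + sample(fx$cfg$n_patches)))        # keep class token first
  ptok <- fx$tok$tokens[perm, ]
  # full variant: gate depends on the 2-D arrangement, so refining the
  # permuted sequence differs from permuting the refined sequence
  out_perm <- far_refine(ptok, blk, fx$cfg)
  perm_out <- far_refine(fx$tok, blk, fx$cfg)[perm, ]
  expect_gt(max(abs(out_perm - perm_out)), 1e-6)
  # negative control: the B1 branch (no gate) is permutation-equivariant
  cfg_b1 <- fx$cfg; cfg_b1$use_se <- FALSE
  out_perm1 <- far_refine(ptok, blk, cfg_b1)
  perm_out1 <- far_refine(fx$tok, blk, cfg_b1)[perm, ]
  expect_lt(max(abs(out_perm1 - perm_out1)), 1e-8)
})

test_that("encoder blocks preserve shape; zero MLP is pure residual", {
  fx <- far_tokens(seed = 11)
  blk <- fx$model$params$blocks[[1]]
  out <- encoder_block(fx$tok, blk, fx$cfg)
  expect_equal(dim(out), c(fx$cfg$n_patches + 1L, fx$cfg$embed_dim))
  blk0 <- blk
  blk0$W_m1[] <- 0; blk0$b_m1[] <- 0; blk0$W_m2[] <- 0; blk0$b_m2[] <- 0
  expect_equal(encoder_block(fx$tok, blk0, fx$cfg),
               far_refine(fx$tok, blk0, fx$cfg))
  # hidden width is mlp_ratio * D
  expect_equal(dim(blk$W_m1), c(8L, 16L))
})

test_that("forward produces a probability distribution; head is affine in the feature", {
  cfg <- tiny_config(depth = 2L)
  model <- fga_model(cfg, seed = 12)
  imgs <- rand_images(3, 16, seed = 12)
  pr <- fga_forward(model, imgs)
  expect_equal(dim(pr), c(3L, 2L))
  expect_equal(rowSums(pr), rep(1, 3), tolerance = 1e-6)
  # zero head -> uniform prediction
  m0 <- model
  m0$params$head_W[] <- 0; m0$params$head_b[] <- 0
  expect_equal(unname(fga_forward(m0, imgs[, , , 1])), c(0.5, 0.5))
  # logits recovered from the exported feature by direct multiplication
  feat <- fga_extract(model, imgs)
  logits <- feat %*% model$params$head_W +
    rep(model$params$head_b, each = 3)
  expect_equal(fgar:::softmax_rows(logits), pr, tolerance = 1e-12)
})

test_that("evaluation mode is deterministic and feature length equals D", {
  model <- fga_model(tiny_config(), seed = 13)
  img <- rand_images(1, 16, seed = 13)[, , , 1]
  expect_identical(fga_forward(model, img), fga_forward(model, img))
  f1 <- fga_extract(model, img)
  expect_identical(f1, fga_extract(model, img))
  expect_length(f1, 16L)
  expect_true(all(is.finite(f1)))
  # default-sized config exports 768-dim features (checked structurally)
  expect_equal(fga_config()$embed_dim, 768L)
})

test_that("one small gradient step decreases the batch loss (all flags on)", {
  cfg <- tiny_config(image_size = 32L, depth = 2L)
  model <- fga_model(cfg, seed = 14)
  x <- rand_images(8, 32, seed = 14)
  y <- rep(1:2, 4)
  out <- fgar:::forward_batch(model, x, mode = "train")
  l0 <- cross_entropy(out$probs, y)
  g <- fgar:::fga_backward(model, out, fgar:::ce_grad_logits(out$probs, y))
  m2 <- model
  m2$params <- fgar:::tree_map2(function(p, gr) p - 1e-5 * gr,
                                model$params, g)
  l1 <- cross_entropy(fgar:::forward_batch(m2, x)$probs, y)
  expect_lt(l1, l0)
})

test_that("checkpoints round-trip and validate config/weight consistency", {
  model <- fga_model(tiny_config(), seed = 15)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path, extra = list(note = "t"))
  back <- load_checkpoint(path)
  expect_equal(back$params, model$params)
  expect_equal(attr(back, "extra")$note, "t")
  # corrupt a weight shape -> loud failure
  bad <- list(config = model$config, params = model$params)
  bad$params$head_W <- matrix(0, 2, 2)
  saveRDS(bad, path)
  expect_error(load_checkpoint(path), "shape mismatch")
})
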