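# Shared fixtures, built in code.  Tiny encoder configurations keep the
# unit tests fast; the session-level cache avoids regenerating the same
# synthetic dataset across test files.

tiny_config <- function(...) {
  args <- list(image_size = 16L, patch_size = 8L, embed_dim = 16L,
               depth = 1L, num_heads = 2L, mlp_ratio = 2,
               se_reduction = 4L, num_classes = 2L)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(fga_config, args)
}

rand_images <- function(n, S, seed = 1) {
  withr::with_seed(seed, array(stats::runif(3 * S * S * n), c(3L, S, S, n)))
}

.fixture_env <- new.env()

# Small synthetic dataset reused across tests (32 x 32 tiles, 30/class).
small_synth <- function() {
  if (is.null(.fixture_env$ds))
    .fixture_env$ds <- generate_dataset(
      synth_spec(image_size = 32L, n_per_class = 30L, seed = 11L))
  .fixture_env$ds
}

# Reference layer norm, independent of the package's implementation.
ref_layer_norm <- function(x, g, b, eps = 1e-6) {
  t(apply(x, 1L, function(r) {
    (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps) * g + b
  }))
}

expect_rel_equal <- function(actual, expected, tol) {
  denom <- max(abs(expected), 1e-8)
  expect_lt(max(abs(actual - expected)) / denom, tol)
}
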