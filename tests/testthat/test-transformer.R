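test_that("self-attention matches the nested-loop oracle", {
  set.seed(202)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    D <- sample(c(4L, 8L, 16L), 1)
    X <- matrix(rnorm(n * D), n, D)
    Wq <- matrix(rnorm(D * D), D, D) / sqrt(D)
    Wk <- matrix(rnorm(D * D), D, D) / sqrt(D)
    Wv <- matrix(rnorm(D * D), D, D) / sqrt(D)
    got <- self_attention(X, Wq, Wk, Wv)
    A <- attr(got, "attention")
    expect_equal(rowSums(A), rep(1, n), tolerance = 1e-6)
    expect_lt(max_rel_dev(unclass(got), oracle_attention(X, Wq, Wk, Wv)), 1e-6)
  }
})

test_that("self-attention degenerate cases", {
  set.seed(3)
  D <- 6L
  Wq <- matrix(rnorm(D * D), D); Wk <- matrix(rnorm(D * D), D)
  Wv <- matrix(rnorm(D * D), D)
  # one token: softmax of a scalar is 1, output is x W_v exactly
  x1 <- matrix(rnorm(D), 1, D)
  expect_equal(unclass(self_attention(x1, Wq, Wk, Wv))[1, ],
               as.vector(x1 %*% Wv), ignore_attr = TRUE)
  # zero projections: uniform attention, every row the column mean of V
  X <- matrix(rnorm(5 * D), 5, D)
  out <- self_attention(X, Wq * 0, Wk * 0, Wv)
  V <- X %*% Wv
  for (i in 1:5) expect_equal(unclass(out)[i, ], colMeans(V), tolerance = 1e-12)
  expect_error(self_attention(X, Wq[1:3, ], Wk, Wv), "mismatch")
})

test_that("multi-head attention equals per-head oracles combined by W_o", {
  set.seed(404)
  for (rep in 1:20) {
    D <- 8L; h <- 2L; n <- 4L
    X <- matrix(rnorm(n * D), n, D)
    params <- list(W_q = matrix(rnorm(D * D), D) / 3,
                   W_k = matrix(rnorm(D * D), D) / 3,
                   W_v = matrix(rnorm(D * D), D) / 3,
                   W_o = matrix(rnorm(D * D), D) / 3)
    got <- multi_head_attention(X, params, h)
    d <- D / h
    heads <- lapply(seq_len(h), function(i) {
      cols <- ((i - 1) * d + 1):(i * d)
      oracle_attention(X, params$W_q[, cols], params$W_k[, cols],
                       params$W_v[, cols])
    })
    want <- do.call(cbind, heads) %*% params$W_o
    expect_lt(max_rel_dev(got, want), 1e-6)
  }
})

test_that("multi-head attention is permutation-equivariant and reduces to
           single-head with identity projection", {
  set.seed(5)
  D <- 6L; n <- 5L
  X <- matrix(rnorm(n * D), n, D)
  params <- list(W_q = matrix(rnorm(D * D), D), W_k = matrix(rnorm(D * D), D),
                 W_v = matrix(rnorm(D * D), D), W_o = diag(D))
  out <- multi_head_attention(X, params, 1L)
  expect_equal(out, unclass(self_attention(X, params$W_q, params$W_k,
                                           params$W_v)),
               ignore_attr = TRUE, tolerance = 1e-12)
  perm <- sample(n)
  expect_equal(multi_head_attention(X[perm, ], params, 2L),
               multi_head_attention(X, params, 2L)[perm, ],
               tolerance = 1e-12)
  expect_error(multi_head_attention(X, params, 4L), "divisible")
})

test_that("transformer block preserves shape and is deterministic", {
  set.seed(6)
  D <- 8L
  p <- transformer_params(D, num_heads = 2L)
  X <- matrix(rnorm(10 * D), 10, D)
  out <- transformer_block_forward(X, p, 2L)
  expect_identical(dim(out), dim(X))
  expect_identical(transformer_block_forward(X, p, 2L), out)
  # zeroed residual branches reduce the block to the identity map
  p0 <- p
  p0$att$W_o[] <- 0; p0$att$b_o[] <- 0
  p0$ffn$W2[] <- 0; p0$ffn$b2[] <- 0
  expect_equal(transformer_block_forward(X, p0, 2L), X, tolerance = 1e-12)
})

test_that("patch tokenization follows the published geometry and inverts", {
  f <- array(rnorm(24 * 24 * 3), c(24, 24, 3))
  seqs <- tokenize_patches(f, 4L)
  expect_length(seqs, 16L)                       # 16 patches
  expect_identical(dim(seqs[[1]]), c(36L, 3L))   # 6^2-token sequences
  expect_equal(untokenize_patches(seqs, 24L, 4L), f)
  expect_error(tokenize_patches(array(0, c(6, 6, 2)), 4L), "not divisible")
})

test_that("classifier head outputs a proper probability pair", {
  set.seed(9)
  cfg <- tiny_config()
  m <- mtsa_net(cfg, seed = 3)
  side <- cfg$input_size %/% 16L
  for (rep in 1:5) {
    f <- array(rnorm(side * side * cfg$stage_channels[5]),
               c(side, side, cfg$stage_channels[5]))
    q <- classify(f, m)
    expect_true(all(q > 0))
    expect_equal(sum(q), 1, tolerance = 1e-9)
    expect_named(q, c("wild", "mutant"))
  }
})

test_that("classifier MLP consumes the pooled grid (24 -> 6 at pool 4)", {
  cfg <- mtsa_config(input_size = 384L,
                     stage_channels = c(2L, 2L, 4L, 4L, 8L),
                     num_heads = 2L, patch_grid = 4L, pool_kernel = 4L,
                     mlp_hidden = 4L)
  m <- mtsa_net(cfg, seed = 4)
  # deepest map is 24x24; pooling with kernel 4 leaves a 6x6 grid
  expect_identical(nrow(m$params$cls$mlp$W1), 6L * 6L * 8L)
})

test_that("classification is invariant to patch processing order", {
  # patches are processed independently with shared weights, so the
  # resulting probability must not depend on any patch ordering; verify by
  # comparing against a manual per-patch recomputation
  set.seed(10)
  cfg <- tiny_config()
  m <- mtsa_net(cfg, seed = 5)
  side <- cfg$input_size %/% 16L
  C <- cfg$stage_channels[5]
  f <- array(rnorm(side * side * C), c(side, side, C))
  seqs <- tokenize_patches(f, cfg$patch_grid)
  p <- m$params$cls
  done <- lapply(rev(seq_along(seqs)), function(k)
    mtsanet:::tblock_fwd(seqs[[k]], p, cfg$num_heads)$out)
  f2 <- untokenize_patches(rev(done), side, cfg$patch_grid)
  direct <- mtsanet:::classifier_fwd_b(array(f, c(1L, dim(f))), p, cfg)
  pooled <- mtsanet:::avgpool_fwd(array(f2, c(1L, dim(f2))), cfg$pool_kernel)
  flat <- matrix(pooled$out, 1L)
  h <- pmax(flat %*% p$mlp$W1 + rep(p$mlp$b1, each = 1), 0)
  logits <- h %*% p$mlp$W2 + rep(p$mlp$b2, each = 1)
  q <- exp(logits - max(logits)); q <- q / sum(q)
  expect_equal(as.vector(direct$q), as.vector(q), tolerance = 1e-9)
})
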