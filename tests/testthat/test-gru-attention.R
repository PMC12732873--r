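test_that("forcing the update gate freezes or bypasses the state", {
  set.seed(1)
  p <- gru_params(3, 2, seed = 2)
  x <- matrix(stats::rnorm(5 * 3), 5, 3)
  # z ~ 1: h_t = h_{t-1} = initial zero state everywhere
  p1 <- p; p1$b[1:2] <- 50
  expect_equal(gru_sequence(x, p1, "forward"), matrix(0, 5, 2),
               tolerance = 1e-10)
  # z ~ 0: h_t is the pure candidate state
  p0 <- p; p0$b[1:2] <- -50
  out <- gru_sequence(x, p0, "forward")
  hprev <- rbind(0, out[-5, , drop = FALSE])
  sig <- function(v) 1 / (1 + exp(-v))
  for (t in 1:5) {
    r <- sig(drop(x[t, ] %*% p0$Wx[, 3:4]) + drop(hprev[t, ] %*% p0$Wh[, 3:4]) +
               p0$b[3:4])
    hc <- tanh(drop(x[t, ] %*% p0$Wx[, 5:6]) +
                 drop((r * hprev[t, ]) %*% p0$Wh[, 5:6]) + p0$b[5:6])
    expect_equal(out[t, ], hc, tolerance = 1e-8)
  }
})

test_that("the recurrence matches an unrolled per-step oracle", {
  set.seed(3)
  for (rep in 1:3) {
    p <- gru_params(3, 3)
    x <- matrix(stats::rnorm(5 * 3), 5, 3)
    expect_equal(gru_sequence(x, p, "forward"), naive_gru(x, p),
                 tolerance = 1e-10)
    # backward direction = forward oracle on the reversed sequence
    expect_equal(gru_sequence(x, p, "backward"),
                 naive_gru(x[5:1, ], p)[5:1, ], tolerance = 1e-10)
  }
})

test_that("bidirectional output is the learned combination of both passes", {
  set.seed(4)
  p <- gru_params(3, 2, output_dim = 4, bidirectional = TRUE)
  x <- matrix(stats::rnorm(6 * 3), 6, 3)
  out <- gru_sequence(x, p, "bidirectional")
  fh <- naive_gru(x, p$fwd)
  bh <- naive_gru(x[6:1, ], p$bwd)[6:1, ]
  expect_equal(out, sweep(fh %*% p$W + bh %*% p$V, 2, p$b, `+`),
               tolerance = 1e-10)
})

test_that("attention weights are row-stochastic and reduce correctly", {
  set.seed(5)
  Q <- matrix(stats::rnorm(12), 4, 3)
  K <- matrix(stats::rnorm(12), 4, 3)
  V <- matrix(stats::rnorm(12), 4, 3)
  aw <- attention_head(Q, K, V, d_K = 3, weights = TRUE)
  expect_true(all(aw$weights >= 0))
  expect_equal(rowSums(aw$weights), rep(1, 4), tolerance = 1e-12)
  # all-equal scores (zero queries) give uniform weights
  u <- attention_head(matrix(0, 4, 3), K, V, d_K = 3, weights = TRUE)
  expect_equal(u$weights, matrix(0.25, 4, 4), tolerance = 1e-12)
  expect_equal(u$out, matrix(rep(colMeans(V), each = 4), 4), tolerance = 1e-12)
  # a single position attends only to itself
  expect_equal(attention_head(Q[1, , drop = FALSE], K[1, , drop = FALSE],
                              V[1, , drop = FALSE], d_K = 3),
               V[1, , drop = FALSE], ignore_attr = TRUE)
  expect_error(attention_head(Q, K, V, d_K = 0), "positive")
})

test_that("attention equals the double-loop score/softmax/sum oracle", {
  set.seed(6)
  for (rep in 1:5) {
    Q <- matrix(stats::rnorm(12), 4, 3)
    K <- matrix(stats::rnorm(12), 4, 3)
    V <- matrix(stats::rnorm(12), 4, 3)
    expect_equal(attention_head(Q, K, V, d_K = 3),
                 naive_attention(Q, K, V, 3), tolerance = 1e-8)
  }
})

test_that("attention is linear in the values with frozen weights", {
  set.seed(7)
  Q <- matrix(stats::rnorm(12), 4, 3)
  K <- matrix(stats::rnorm(12), 4, 3)
  V <- matrix(stats::rnorm(12), 4, 3)
  aw <- attention_head(Q, K, V, d_K = 3, weights = TRUE)
  perm <- c(3, 1, 4, 2)
  expect_equal(aw$weights[, perm] %*% V[perm, ], aw$out, tolerance = 1e-12)
  # doubling the values doubles the output
  expect_equal(attention_head(Q, K, 2 * V, d_K = 3), 2 * aw$out,
               tolerance = 1e-12)
})

test_that("encoder layers preserve shape and normalize their output rows", {
  set.seed(8)
  p <- encoder_params(4, heads = 2, gru_hidden = 2, ff_mult = 1)
  x <- matrix(stats::rnorm(6 * 4), 6, 4)
  out <- encoder_layer(x, p)
  expect_equal(dim(out), c(6, 4))
  # with identity affine parameters, each row is standardized
  expect_equal(rowMeans(out), rep(0, 6), tolerance = 1e-8)
  expect_equal(apply(out, 1, function(r) mean(r^2)), rep(1, 6),
               tolerance = 1e-3)
  expect_error(encoder_params(5, heads = 2), "divisible")
})

test_that("a single-head layer equals the manual composition of its parts", {
  set.seed(9)
  p <- encoder_params(4, heads = 1, gru_hidden = 3, ff_mult = 1)
  x <- matrix(stats::rnorm(5 * 4), 5, 4)
  hq <- gru_sequence(x, p$heads_qkv[[1]]$q, "bidirectional")
  hk <- gru_sequence(x, p$heads_qkv[[1]]$k, "bidirectional")
  hv <- gru_sequence(x, p$heads_qkv[[1]]$v, "bidirectional")
  att <- attention_head(hq, hk, hv, d_K = p$head_dim)
  a3 <- array(att, c(1, 5, 4))
  conv <- promkan:::conv1d_fwd(a3, p$conv_a, 3L)$out +
    promkan:::conv1d_fwd(a3, p$conv_b, 3L)$out
  Z <- promkan:::dense_fwd(promkan:::as_mat(conv), p$reduce)$out
  ff <- promkan:::dense_fwd(pmax(promkan:::dense_fwd(Z, p$ff1)$out, 0), p$ff2)$out
  pre <- promkan:::as_arr(Z + ff, 1L, 5L)
  manual <- promkan:::ln_fwd(pre, p$ln)$out
  expect_equal(encoder_layer(x, p), matrix(manual[1, , ], 5, 4),
               tolerance = 1e-10)
})

test_that("the encoder stack composes serially", {
  set.seed(10)
  p1 <- encoder_params(4, heads = 2, gru_hidden = 2, ff_mult = 1)
  p2 <- encoder_params(4, heads = 2, gru_hidden = 2, ff_mult = 1)
  x <- matrix(stats::rnorm(6 * 4), 6, 4)
  expect_equal(encoder_stack(x, list(p1)), encoder_layer(x, p1))
  expect_equal(encoder_stack(x, list(p1, p2)),
               encoder_layer(encoder_layer(x, p1), p2))
  expect_error(encoder_stack(x, list()), "at least one")
})

test_that("the default model instantiates four encoder layers with four heads", {
  m <- promkan_build(promkan_config(), seed = 1)
  expect_length(m$params$encoders, 4L)
  expect_equal(m$params$encoders[[1]]$heads, 4L)
  expect_length(m$params$encoders[[1]]$heads_qkv, 4L)
})
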