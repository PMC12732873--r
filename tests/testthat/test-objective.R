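test_that("cross-entropy reproduces closed forms and the summation loop", {
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2))
  expect_lt(cross_entropy(c(1, 0), c(1, 0)), 1e-6)
  expect_error(cross_entropy(c(1, 0), c(0.9, 0.3)), "sum to 1")
  expect_error(cross_entropy(c(1, 0, 0), c(0.5, 0.5)), "length")
  set.seed(1)
  for (rep in 1:10) {
    K <- sample(2:5, 1)
    y <- as.numeric(seq_len(K) == sample(K, 1))
    p <- stats::runif(K); p <- p / sum(p)
    loop <- 0
    for (i in seq_len(K)) loop <- loop - y[i] * log(max(p[i], 1e-7))
    expect_equal(cross_entropy(y, p), loop, tolerance = 1e-12)
  }
})

test_that("smoothed loss follows its printed form, including the asymmetry", {
  expect_equal(smooth_ce(1, 0.5, epsilon = 0), log(2))
  # a negative example contributes only through the epsilon term
  expect_equal(smooth_ce(0, 0.5, epsilon = 0), 0)
  expect_equal(smooth_ce(0, 0.5, epsilon = 0.1), -0.1 * log(0.5))
  expect_equal(smooth_ce(1, 0.8, epsilon = 0.1), -0.9 * log(0.8))
  expect_error(smooth_ce(1, 0.5, epsilon = 1), "epsilon")
  expect_error(smooth_ce(1, 0.5, epsilon = -0.1), "epsilon")
})

test_that("regularizer adds exactly lambda times the squared distribution norm", {
  expect_equal(reg_smooth_loss(1, 0.5, epsilon = 0.1, lambda = 0),
               smooth_ce(1, 0.5, 0.1))
  expect_equal(reg_smooth_loss(1, 0.5, epsilon = 0.1, lambda = 1) -
                 smooth_ce(1, 0.5, 0.1), 0.5)    # 0.25 + 0.25
  set.seed(2)
  y <- rbinom(20, 1, 0.5)
  p <- stats::runif(20, 0.05, 0.95)
  loop <- mean(sapply(seq_along(y), function(i) {
    smooth_ce(y[i], p[i], 0.1) + 1e-3 * (p[i]^2 + (1 - p[i])^2)
  }))
  expect_equal(reg_smooth_loss(y, p, 0.1, 1e-3), loop, tolerance = 1e-12)
  expect_error(reg_smooth_loss(1, 0.5, lambda = -1), "lambda")
})

test_that("with smoothing and regularization off the loss is binary CE", {
  p <- seq(0.01, 0.99, by = 0.07)
  expect_equal(reg_smooth_loss(1, p, 0, 0, reduce = FALSE), -log(p))
  # at epsilon = 0 the y = 0 branch is identically zero (printed form)
  expect_equal(reg_smooth_loss(0, p, 0, 0, reduce = FALSE), rep(0, length(p)))
})

test_that("analytic probability gradient matches central differences", {
  set.seed(3)
  for (rep in 1:20) {
    y <- rbinom(1, 1, 0.5)
    p <- stats::runif(1, 0.05, 0.95)
    eps <- stats::runif(1, 0, 0.3)
    lam <- stats::runif(1, 0, 0.01)
    h <- 1e-6
    num <- (reg_smooth_loss(y, p + h, eps, lam) -
              reg_smooth_loss(y, p - h, eps, lam)) / (2 * h)
    expect_equal(promkan:::reg_smooth_grad(y, p, eps, lam), num,
                 tolerance = 1e-5)
  }
})

test_that("the probability-norm penalty keeps the minimizer strictly interior", {
  # under the printed asymmetric smoothing the epsilon term vanishes at
  # y = 1, so overconfidence suppression comes from the L2 distribution
  # penalty: the minimizer is interior once lambda exceeds (1 - epsilon)/2
  grid <- seq(0.001, 0.999, by = 0.001)
  loss <- reg_smooth_loss(1, grid, epsilon = 0.1, lambda = 1,
                          reduce = FALSE)
  best <- grid[which.min(loss)]
  expect_lt(best, 1)
  expect_gt(best, 0.5)
  # without smoothing or regularization the minimum sits at the boundary
  plain <- reg_smooth_loss(1, grid, epsilon = 0, lambda = 0, reduce = FALSE)
  expect_equal(grid[which.min(plain)], max(grid))
})
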