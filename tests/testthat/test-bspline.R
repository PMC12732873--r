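test_that("degree-0 bases are interval indicators", {
  g <- spline_grid(c(0, 1, 2), degree = 0)
  expect_equal(bspline_bases(0.5, g), matrix(c(1, 0), 1))
  expect_equal(bspline_bases(1.5, g), matrix(c(0, 1), 1))
  expect_equal(bspline_bases(2, g), matrix(c(0, 1), 1))  # right end closed
})

test_that("bases are a non-negative partition of unity with local support", {
  set.seed(31)
  for (deg in 0:3) {
    for (rep in 1:4) {
      nodes <- sort(stats::runif(6, -2, 2))
      nodes <- nodes + seq_along(nodes) * 1e-3     # ensure strict increase
      g <- spline_grid(nodes, degree = deg)
      x <- stats::runif(50, min(nodes), max(nodes))
      B <- bspline_bases(x, g)
      expect_equal(ncol(B), g$n_basis)
      expect_true(all(B >= -1e-12))
      expect_equal(rowSums(B), rep(1, 50), tolerance = 1e-10)
      # local support: each basis lives on k+1 consecutive intervals
      t <- g$ext_knots
      for (i in seq_len(g$n_basis)) {
        outside <- x < t[i] | x > t[i + deg + 1]
        if (any(outside)) expect_true(all(abs(B[outside, i]) < 1e-12))
      }
    }
  }
})

test_that("recursion agrees with an independently coded Cox-de Boor oracle", {
  set.seed(77)
  for (rep in 1:5) {
    nodes <- cumsum(c(stats::runif(1, -2, 0), stats::runif(5, 0.1, 1)))
    g <- spline_grid(nodes, degree = 3)
    x <- stats::runif(10, min(nodes), max(nodes))
    B <- bspline_bases(x, g)
    for (j in seq_along(x)) {
      expect_equal(B[j, ], naive_bspline_row(x[j], g$ext_knots, 3),
                   tolerance = 1e-10)
    }
  }
})

test_that("basis derivatives match central finite differences", {
  g <- spline_grid(seq(-1, 1, length.out = 6), degree = 3)
  x <- seq(-0.9, 0.9, length.out = 7)
  bd <- bspline_bases(x, g, derivative = TRUE)
  h <- 1e-6
  num <- (bspline_bases(x + h, g) - bspline_bases(x - h, g)) / (2 * h)
  expect_equal(bd$deriv, num, tolerance = 1e-6)
})

test_that("grid mixing applies the 0.02 / 0.98 convex rule node-wise", {
  expect_equal(mix_grids(rep(1, 6), rep(0, 6)), rep(0.02, 6))
  g <- seq(-1, 1, length.out = 6)
  expect_equal(mix_grids(g, g), g)                    # fixed point
  expect_equal(mix_grids(c(1, 2), c(3, 4), mix_uniform = 0.5), c(2, 3))
  expect_error(mix_grids(1:3, 1:4), "same number")
})

test_that("update_grid blends range-uniform and quantile nodes", {
  layer <- kan_linear(2, 3, grid_size = 5, init_seed = 1)
  layer$adaptive_update <- TRUE
  set.seed(5)
  batch <- cbind(stats::rexp(200), stats::rnorm(200))   # skewed + symmetric
  g <- update_grid(batch, layer)
  probs <- seq(0, 1, length.out = 6)
  for (c in 1:2) {
    v <- batch[, c]
    expected <- 0.02 * seq(min(v), max(v), length.out = 6) +
      0.98 * naive_quantile7(v, probs)
    expect_equal(g[c, ], expected, tolerance = 1e-10)
    expect_true(all(diff(g[c, ]) >= 0))
  }
})

test_that("uniformly spread batches leave the grid essentially unchanged", {
  layer <- kan_linear(1, 1, grid_size = 5, init_seed = 2)
  layer$adaptive_update <- TRUE
  batch <- matrix(seq(-1, 1, length.out = 201), ncol = 1)
  g <- update_grid(batch, layer)
  # uniform and adaptive candidates coincide, so their mixture is either
  expect_equal(g[1, ], seq(-1, 1, length.out = 6), tolerance = 1e-10)
})

test_that("the update is dormant unless adaptive updating is enabled", {
  layer <- kan_linear(1, 1, init_seed = 3)       # adaptive_update = FALSE
  batch <- matrix(stats::rexp(50), ncol = 1)
  expect_equal(update_grid(batch, layer), layer$grid)
  expect_false(isTRUE(all.equal(update_grid(batch, layer, force = TRUE),
                                layer$grid)))
  expect_error(update_grid(matrix(0, 0, 1), layer), "non-empty")
})
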