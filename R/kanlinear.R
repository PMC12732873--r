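#' Kolmogorov-Arnold linear layer
#'
#' A KANLinear layer maps an `in_dim` feature vector to `out_dim` outputs as
#' the sum of a plain linear transformation and a learned spline
#' transformation:
#'
#' `output(x) = x . base_weight + spline_bases(x) . spline_weight`
#'
#' Each input feature is expanded through its own B-spline basis (degree `k`,
#' `G` grid intervals, so `G + k` basis functions per feature); the univariate
#' spline maps play the role of the inner functions of the Kolmogorov-Arnold
#' representation, and the outer combination is absorbed into the output
#' dimension of `spline_weight`.
#'
#' @param in_dim,out_dim layer dimensions.
#' @param grid_size number of grid intervals `G` (default 5).
#' @param degree spline degree `k` (default 3).
#' @param grid_range initial knot range, shared by all features
#'   (default `c(-1, 1)`).
#' @param grid_mix_uniform uniform-grid weight used by [update_grid()]
#'   (default 0.02).
#' @param adaptive_update whether [update_grid()] actually moves the knots
#'   (default `FALSE`; the update rule stays available but is disabled for
#'   training stability).
#' @param init_seed optional seed for weight initialization.
#' @return an object of class `kan_linear` holding `base_weight`
#'   (`in_dim x out_dim`), `spline_weight` (`(in_dim * n_basis) x out_dim`,
#'   feature-major rows) and the per-feature knot `grid`
#'   (`in_dim x (G + 1)` matrix of nodes).
#' @export
kan_linear <- function(in_dim, out_dim, grid_size = 5L, degree = 3L,
                       grid_range = c(-1, 1), grid_mix_uniform = 0.02,
                       adaptive_update = FALSE, init_seed = NULL) {
  if (!is.null(init_seed)) set.seed(init_seed)
  nb <- grid_size + degree
  p <- list(
    in_dim = as.integer(in_dim), out_dim = as.integer(out_dim),
    grid_size = as.integer(grid_size), degree = as.integer(degree),
    n_basis = as.integer(nb),
    grid_mix_uniform = grid_mix_uniform,
    adaptive_update = isTRUE(adaptive_update),
    base_weight = matrix(stats::rnorm(in_dim * out_dim, sd = sqrt(2 / in_dim)),
                         in_dim, out_dim),
    spline_weight = matrix(stats::rnorm(in_dim * nb * out_dim,
                                        sd = 0.1 / sqrt(in_dim)),
                           in_dim * nb, out_dim),
    grid = matrix(rep(seq(grid_range[1], grid_range[2],
                          length.out = grid_size + 1L), each = in_dim),
                  in_dim, grid_size + 1L)
  )
  class(p) <- "kan_linear"
  p
}

#' Forward map of a KANLinear layer
#'
#' Evaluates `x . base_weight + spline_bases(x) . spline_weight` for a single
#' feature vector or a matrix of row vectors.
#'
#' @param x numeric vector of length `in_dim`, or matrix with `in_dim`
#'   columns.
#' @param params a [kan_linear()] layer.
#' @return numeric vector of length `out_dim` (or matrix of rows).
#' @export
kan_linear_forward <- function(x, params) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, 1) else as.matrix(x)
  if (ncol(xm) != params$in_dim) {
    stop("input has ", ncol(xm), " features, layer expects ", params$in_dim)
  }
  out <- kan_fwd(xm, params)$out
  if (vec) drop(out) else out
}

# internal forward keeping caches for backprop
kan_fwd <- function(xm, params, need_deriv = TRUE) {
  n <- nrow(xm); cin <- params$in_dim; nb <- params$n_basis
  Bflat <- matrix(0, n, cin * nb)
  Dflat <- if (need_deriv) matrix(0, n, cin * nb) else NULL
  for (c in seq_len(cin)) {
    g <- spline_grid(params$grid[c, ], params$degree)
    cols <- ((c - 1L) * nb + 1L):(c * nb)
    if (need_deriv) {
      bd <- bspline_bases(xm[, c], g, derivative = TRUE)
      Bflat[, cols] <- bd$basis
      Dflat[, cols] <- bd$deriv
    } else {
      Bflat[, cols] <- bspline_bases(xm[, c], g)
    }
  }
  out <- xm %*% params$base_weight + Bflat %*% params$spline_weight
  list(out = out, x = xm, B = Bflat, D = Dflat)
}

# gradient of the KANLinear map; returns input gradient and weight gradients
kan_bwd <- function(cache, params, dout) {
  dbase <- crossprod(cache$x, dout)
  dspline <- crossprod(cache$B, dout)
  dB <- dout %*% t(params$spline_weight)
  nb <- params$n_basis
  dx <- dout %*% t(params$base_weight)
  for (c in seq_len(params$in_dim)) {
    cols <- ((c - 1L) * nb + 1L):(c * nb)
    dx[, c] <- dx[, c] + rowSums(dB[, cols, drop = FALSE] *
                                   cache$D[, cols, drop = FALSE])
  }
  list(dx = dx, base_weight = dbase, spline_weight = dspline)
}

#' Adaptive knot-grid update
#'
#' Recomputes the per-feature knot positions from a batch of layer inputs:
#' the adaptive candidate places the `G + 1` nodes at evenly spaced empirical
#' quantiles of the batch (linear interpolation between order statistics),
#' the uniform candidate spaces them evenly over the batch range, and the new
#' grid is their convex mixture via [mix_grids()] with uniform weight
#' `grid_mix_uniform` (default 0.02, adaptive weight 0.98). When the layer's
#' `adaptive_update` flag is `FALSE` the current grid is returned unchanged,
#' the rule stays dormant.
#'
#' @param batch numeric matrix of layer inputs (rows = samples, columns =
#'   features; a vector is treated as a single feature).
#' @param params a [kan_linear()] layer.
#' @param force apply the update even if the layer has `adaptive_update =
#'   FALSE` (used for direct inspection of the rule).
#' @return the updated node matrix (`in_dim x (G + 1)`), rows non-decreasing.
#' @export
update_grid <- function(batch, params, force = FALSE) {
  if (is.null(dim(batch))) batch <- matrix(batch, ncol = 1L)
  if (nrow(batch) == 0L) stop("grid update requires a non-empty batch")
  if (!params$adaptive_update && !force) return(params$grid)
  if (ncol(batch) != params$in_dim) {
    stop("batch has ", ncol(batch), " features, layer expects ", params$in_dim)
  }
  probs <- seq(0, 1, length.out = params$grid_size + 1L)
  new_grid <- params$grid
  for (c in seq_len(params$in_dim)) {
    v <- batch[, c]
    adaptive <- stats::quantile(v, probs, names = FALSE, type = 7)
    uniform <- seq(min(v), max(v), length.out = params$grid_size + 1L)
    new_grid[c, ] <- mix_grids(uniform, adaptive, params$grid_mix_uniform)
  }
  new_grid
}
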