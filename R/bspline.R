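#' B-spline knot grid
#'
#' Holds the interior knot positions and degree of a one-dimensional B-spline
#' basis, plus the extended knot vector obtained by continuing the first and
#' last knot spacings `degree` times beyond each end. With `G` grid intervals
#' and degree `k` the basis has `G + k` functions; inside the interior knot
#' range they are non-negative, locally supported and sum to one.
#'
#' @param nodes strictly increasing numeric vector of knot positions
#'   (`G + 1` values for `G` intervals).
#' @param degree polynomial degree `k >= 0` (default 3, cubic).
#' @return an object of class `spline_grid` with fields `nodes`, `degree`,
#'   `ext_knots` and `n_basis`.
#' @examples
#' g <- spline_grid(seq(-1, 1, length.out = 6), degree = 3)
#' g$n_basis   # 5 intervals + degree 3 = 8 basis functions
#' @export
spline_grid <- function(nodes, degree = 3L) {
  nodes <- as.numeric(nodes)
  degree <- as.integer(degree)
  if (degree < 0L) stop("degree must be non-negative")
  if (length(nodes) < 2L) stop("need at least two knot positions")
  if (any(diff(nodes) < 0)) stop("knot positions must be non-decreasing")
  structure(list(nodes = nodes,
                 degree = degree,
                 ext_knots = extend_knots(nodes, degree),
                 n_basis = length(nodes) - 1L + degree),
            class = "spline_grid")
}

# continue the boundary spacings k times beyond each end (uniform-style
# extension rather than repeated knots, so the basis stays C^{k-1} at the ends)
extend_knots <- function(nodes, degree) {
  if (degree == 0L) return(nodes)
  h1 <- nodes[2] - nodes[1]
  h2 <- nodes[length(nodes)] - nodes[length(nodes) - 1]
  c(nodes[1] - rev(seq_len(degree)) * h1,
    nodes,
    nodes[length(nodes)] + seq_len(degree) * h2)
}

#' Evaluate a B-spline basis
#'
#' Computes all basis functions of a [spline_grid()] at each element of `x`
#' by the Cox-de Boor recursion. Intervals of zero length (coincident knots)
#' use the 0/0 = 0 convention. Values outside the extended knot range get an
#' all-zero row.
#'
#' @param x numeric vector of evaluation points (finite).
#' @param grid a [spline_grid()].
#' @param derivative if `TRUE`, also return first derivatives.
#' @return numeric matrix `length(x)` by `grid$n_basis`; with
#'   `derivative = TRUE`, a list with elements `basis` and `deriv`.
#' @export
bspline_bases <- function(x, grid, derivative = FALSE) {
  stopifnot(inherits(grid, "spline_grid"))
  if (any(!is.finite(x))) stop("B-spline evaluation requires finite inputs")
  t <- grid$ext_knots
  k <- grid$degree
  m <- length(t)
  n <- length(x)
  # degree-0: interval indicators, half-open except the final interval
  B <- matrix(0, n, m - 1L)
  for (i in seq_len(m - 1L)) {
    if (i < m - 1L) B[, i] <- as.numeric(x >= t[i] & x < t[i + 1L])
    else B[, i] <- as.numeric(x >= t[i] & x <= t[i + 1L])
  }
  Bprev <- NULL
  if (k > 0L) {
    for (d in seq_len(k)) {
      nb <- m - 1L - d
      Bnew <- matrix(0, n, nb)
      for (i in seq_len(nb)) {
        den1 <- t[i + d] - t[i]
        den2 <- t[i + d + 1L] - t[i + 1L]
        left <- if (den1 > 0) (x - t[i]) / den1 * B[, i] else 0
        right <- if (den2 > 0) (t[i + d + 1L] - x) / den2 * B[, i + 1L] else 0
        Bnew[, i] <- left + right
      }
      if (d == k) Bprev <- B
      B <- Bnew
    }
  }
  if (!derivative) return(B)
  D <- matrix(0, n, ncol(B))
  if (k > 0L) {
    for (i in seq_len(ncol(B))) {
      den1 <- t[i + k] - t[i]
      den2 <- t[i + k + 1L] - t[i + 1L]
      term1 <- if (den1 > 0) Bprev[, i] / den1 else 0
      term2 <- if (den2 > 0) Bprev[, i + 1L] / den2 else 0
      D[, i] <- k * (term1 - term2)
    }
  }
  list(basis = B, deriv = D)
}

#' Mix uniform and adaptive knot grids
#'
#' The convex knot-update rule used by the adaptive grid refresh:
#' `new = w * uniform + (1 - w) * adaptive`, with the uniform share `w`
#' defaulting to 0.02 (so the data-adaptive quantile grid carries weight
#' 0.98). Applied node-wise; both inputs must have equal length.
#'
#' @param grid_uniform numeric vector of evenly spaced candidate nodes.
#' @param grid_adaptive numeric vector of quantile-based candidate nodes.
#' @param mix_uniform weight of the uniform grid, in `[0, 1]` (default 0.02).
#' @return numeric vector of mixed node positions.
#' @examples
#' mix_grids(rep(1, 6), rep(0, 6))   # every node 0.02
#' @export
mix_grids <- function(grid_uniform, grid_adaptive, mix_uniform = 0.02) {
  if (length(grid_uniform) != length(grid_adaptive)) {
    stop("uniform and adaptive grids must have the same number of nodes")
  }
  if (mix_uniform < 0 || mix_uniform > 1) stop("mix_uniform must be in [0, 1]")
  mix_uniform * grid_uniform + (1 - mix_uniform) * grid_adaptive
}
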