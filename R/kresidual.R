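#' KRAN residual block
#'
#' One block of the Kresidual stage. The main branch processes the incoming
#' feature map with a kernel-3 convolution, batch normalization and ReLU,
#' then applies a KANLinear layer position-wise across channels (every
#' sequence position's channel vector is passed through the same learned
#' spline map). The shortcut branch is a 1x1 convolution with batch
#' normalization, aligning channel and position dimensions. The block output
#' is `ReLU(main + shortcut)`.
#'
#' @param channels channel width of the block (input and output).
#' @param grid_size,degree B-spline grid intervals and degree of the
#'   embedded KANLinear layer.
#' @param seed optional RNG seed.
#' @return a `kran_block_params` list.
#' @export
kran_block_params <- function(channels = 128L, grid_size = 5L, degree = 3L,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- list(
    channels = as.integer(channels),
    main_conv = conv1d_init(3L, channels, channels),
    main_bn = bn_init(channels),
    kan = kan_linear(channels, channels, grid_size = grid_size,
                     degree = degree),
    short_conv = conv1d_init(1L, channels, channels),
    short_bn = bn_init(channels),
    state = list(main_bn = bn_state_init(channels),
                 short_bn = bn_state_init(channels))
  )
  class(p) <- "kran_block_params"
  p
}

#' Forward pass of one KRAN block
#'
#' @param x feature map (`positions x channels` matrix or
#'   `[batch, positions, channels]` array).
#' @param p a [kran_block_params()] object.
#' @param mode `"train"` or `"infer"`.
#' @return feature map of identical shape, entries non-negative.
#' @export
kran_block_forward <- function(x, p, mode = "infer") {
  mat_in <- is.matrix(x)
  if (mat_in) x <- array(x, c(1L, dim(x)))
  out <- kran_fwd(x, p, mode)$out
  if (mat_in) matrix(out[1, , ], dim(out)[2], dim(out)[3]) else out
}

kran_fwd <- function(x, p, mode) {
  d <- dim(x); n <- d[1]; L <- d[2]
  if (d[3] != p$channels) {
    stop("input has ", d[3], " channels, block expects ", p$channels)
  }
  mc <- conv1d_fwd(x, p$main_conv, 3L)
  mb <- bn_fwd(mc$out, p$main_bn, p$state$main_bn, mode)
  mr <- relu_fwd(mb$out)
  kf <- kan_fwd(as_mat(mr$out), p$kan)
  main <- as_arr(kf$out, n, L)
  sc <- conv1d_fwd(x, p$short_conv, 1L)
  sb <- bn_fwd(sc$out, p$short_bn, p$state$short_bn, mode)
  sum_ <- main + sb$out
  out <- relu_fwd(sum_)
  list(out = out$out,
       cache = list(mc = mc, mb = mb, mr = mr, kf = kf, sc = sc, sb = sb,
                    relu = out$cache, n = n, L = L),
       state = list(main_bn = mb$state, short_bn = sb$state),
       kan_input = kf$x)
}

kran_bwd <- function(cache, p, dout) {
  n <- cache$n; L <- cache$L
  g <- list()
  dsum <- relu_bwd(cache$relu, dout)
  # shortcut branch
  sbb <- bn_bwd(cache$sb$cache, p$short_bn, dsum)
  g$short_bn <- sbb[c("gamma", "beta")]
  scb <- conv1d_bwd(cache$sc$cache, p$short_conv, sbb$dx)
  g$short_conv <- scb[c("W", "b")]
  # main branch
  kb <- kan_bwd(cache$kf, p$kan, as_mat(dsum))
  g$kan <- kb[c("base_weight", "spline_weight")]
  dmr <- relu_bwd(cache$mr$cache, as_arr(kb$dx, n, L))
  mbb <- bn_bwd(cache$mb$cache, p$main_bn, dmr)
  g$main_bn <- mbb[c("gamma", "beta")]
  mcb <- conv1d_bwd(cache$mc$cache, p$main_conv, mbb$dx)
  g$main_conv <- mcb[c("W", "b")]
  list(dx = mcb$dx + scb$dx, grads = g)
}

#' Serial Kresidual stage
#'
#' Applies a list of KRAN blocks in series (default depth 4), each block's
#' output ReLU-activated, progressively building higher-order nonlinear
#' features on top of the multi-scale convolutional map.
#'
#' @param x_m feature map from [multiscale_forward()].
#' @param blocks non-empty list of [kran_block_params()].
#' @param mode `"train"` or `"infer"`.
#' @return feature map with unchanged position and channel dimensions.
#' @export
kresidual_forward <- function(x_m, blocks, mode = "infer") {
  if (inherits(blocks, "kran_block_params")) blocks <- list(blocks)
  if (length(blocks) < 1L) stop("need at least one KRAN block")
  for (b in blocks) x_m <- kran_block_forward(x_m, b, mode)
  x_m
}
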