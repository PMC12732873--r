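#' Multi-scale convolutional front end
#'
#' Builds the parameters of the first feature-extraction stage: four parallel
#' 1-D convolutions with kernel sizes 3, 5, 7 and 9 (and per-branch filter
#' counts, default 32/48/64/80, giving larger receptive fields more
#' capacity), channel-wise concatenation, batch normalization, max pooling
#' (window 2, stride 2) and a kernel-3 convolution with ReLU that compresses
#' the map to `trunk_channels` (default 128) channels.
#'
#' @param in_channels input channel count (7 for the hybrid encoding).
#' @param kernels kernel sizes of the parallel branches.
#' @param filters filter count per branch (same length as `kernels`).
#' @param trunk_channels output channel count of the compressing convolution.
#' @param seed optional RNG seed.
#' @return a `multiscale_params` list (weights plus batch-norm state).
#' @export
multiscale_params <- function(in_channels = 7L, kernels = c(3L, 5L, 7L, 9L),
                              filters = c(32L, 48L, 64L, 80L),
                              trunk_channels = 128L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(kernels) == length(filters))
  concat <- sum(filters)
  p <- list(
    kernels = as.integer(kernels), filters = as.integer(filters),
    trunk_channels = as.integer(trunk_channels),
    branches = mapply(function(k, f) conv1d_init(k, in_channels, f),
                      kernels, filters, SIMPLIFY = FALSE),
    bn = bn_init(concat),
    trunk = conv1d_init(3L, concat, trunk_channels),
    state = list(bn = bn_state_init(concat))
  )
  class(p) <- "multiscale_params"
  p
}

#' Forward pass of the multi-scale convolution and pooling stage
#'
#' @param enc hybrid-encoded input: an `encoded_matrix` (`n x 7`), a plain
#'   `positions x channels` matrix, or a `[batch, positions, channels]`
#'   array.
#' @param p a [multiscale_params()] object.
#' @param mode `"train"` (batch statistics for normalization) or `"infer"`
#'   (running averages).
#' @return feature map with `ceiling(positions / 2)` positions and
#'   `trunk_channels` channels.
#' @export
multiscale_forward <- function(enc, p, mode = "infer") {
  mat_in <- is.matrix(enc)
  x <- if (mat_in) array(unclass(enc), c(1L, dim(enc))) else enc
  r <- multiscale_fwd(x, p, mode)
  out <- r$out
  if (mat_in) matrix(out[1, , ], dim(out)[2], dim(out)[3]) else out
}

multiscale_fwd <- function(x, p, mode) {
  d <- dim(x); n <- d[1]; L <- d[2]
  if (L < max(p$kernels)) {
    stop("sequence length ", L, " shorter than the largest kernel ",
         max(p$kernels))
  }
  bc <- vector("list", length(p$kernels))
  concat <- array(0, c(n, L, sum(p$filters)))
  off <- 0L
  for (i in seq_along(p$kernels)) {
    bc[[i]] <- conv1d_fwd(x, p$branches[[i]], p$kernels[i])
    concat[, , off + seq_len(p$filters[i])] <- bc[[i]]$out
    off <- off + p$filters[i]
  }
  bn <- bn_fwd(concat, p$bn, p$state$bn, mode)
  mp <- maxpool_fwd(bn$out)
  tr <- conv1d_fwd(mp$out, p$trunk, 3L)
  rl <- relu_fwd(tr$out)
  list(out = rl$out,
       cache = list(bc = bc, bn = bn, mp = mp, tr = tr, rl = rl, n = n, L = L),
       state = list(bn = bn$state))
}

multiscale_bwd <- function(cache, p, dout) {
  g <- list()
  dtr <- relu_bwd(cache$rl$cache, dout)
  tb <- conv1d_bwd(cache$tr$cache, p$trunk, dtr)
  g$trunk <- tb[c("W", "b")]
  dmp <- maxpool_bwd(cache$mp$cache, tb$dx)
  bb <- bn_bwd(cache$bn$cache, p$bn, dmp)
  g$bn <- bb[c("gamma", "beta")]
  dconcat <- bb$dx
  dx <- NULL
  g$branches <- vector("list", length(p$kernels))
  off <- 0L
  for (i in seq_along(p$kernels)) {
    di <- dconcat[, , off + seq_len(p$filters[i]), drop = FALSE]
    cb <- conv1d_bwd(cache$bc[[i]]$cache, p$branches[[i]], di)
    g$branches[[i]] <- cb[c("W", "b")]
    dx <- if (is.null(dx)) cb$dx else dx + cb$dx
    off <- off + p$filters[i]
  }
  list(dx = dx, grads = g)
}
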