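#' Scaled dot-product attention head
#'
#' Computes, for every query position i, scores
#' `S[i, j] = <q_i, k_j> / sqrt(d_K)`, softmax-normalizes each score row and
#' returns the weight-averaged values `head_i = sum_j A[i, j] v_j`. Attention
#' weight rows are non-negative and sum to one for any input.
#'
#' @param hQ,hK,hV query / key / value feature maps: `positions x d`
#'   matrices or `[batch, positions, d]` arrays with matching position counts.
#' @param d_K positive scaling dimension (defaults to `ncol(hK)`).
#' @param weights if `TRUE`, also return the attention weight matrices.
#' @return the attended feature map (same shape as `hV`); with
#'   `weights = TRUE`, a list with `out` and `weights`.
#' @export
attention_head <- function(hQ, hK, hV, d_K = NULL, weights = FALSE) {
  mat_in <- is.matrix(hQ)
  if (mat_in) {
    hQ <- array(hQ, c(1L, nrow(hQ), ncol(hQ)))
    hK <- array(hK, c(1L, dim(hK)))
    hV <- array(hV, c(1L, dim(hV)))
  }
  if (is.null(d_K)) d_K <- dim(hK)[3]
  if (d_K <= 0) stop("d_K must be positive")
  r <- attn_fwd(hQ, hK, hV, d_K)
  out <- r$out
  if (mat_in) {
    out <- matrix(out[1, , ], dim(out)[2], dim(out)[3])
    if (weights) return(list(out = out, weights = r$cache$A[[1]]))
    return(out)
  }
  if (weights) list(out = out, weights = r$cache$A) else out
}

attn_fwd <- function(hQ, hK, hV, d_K) {
  d <- dim(hQ); n <- d[1]; L <- d[2]
  dv <- dim(hV)[3]
  out <- array(0, c(n, L, dv))
  A <- vector("list", n)
  sc <- 1 / sqrt(d_K)
  for (i in seq_len(n)) {
    Q <- matrix(hQ[i, , ], L); K <- matrix(hK[i, , ], L); V <- matrix(hV[i, , ], L)
    S <- (Q %*% t(K)) * sc
    A[[i]] <- softmax_rows(S)
    out[i, , ] <- A[[i]] %*% V
  }
  list(out = out, cache = list(A = A, hQ = hQ, hK = hK, hV = hV,
                               sc = sc, n = n, L = L))
}

attn_bwd <- function(cache, dout) {
  n <- cache$n; L <- cache$L
  dQa <- array(0, dim(cache$hQ))
  dKa <- array(0, dim(cache$hK))
  dVa <- array(0, dim(cache$hV))
  for (i in seq_len(n)) {
    A <- cache$A[[i]]
    dO <- matrix(dout[i, , ], L)
    V <- matrix(cache$hV[i, , ], L)
    dVa[i, , ] <- crossprod(A, dO)
    dA <- dO %*% t(V)
    dS <- softmax_rows_bwd(A, dA) * cache$sc
    dQa[i, , ] <- dS %*% matrix(cache$hK[i, , ], L)
    dKa[i, , ] <- crossprod(dS, matrix(cache$hQ[i, , ], L))
  }
  list(dQ = dQa, dK = dKa, dV = dVa)
}

# ---- encoder layer ---------------------------------------------------------
# Per head: Q, K, V each produced by its own bidirectional GRU; scaled
# dot-product attention; heads concatenated; two parallel kernel-3
# convolutions summed; linear reduction back to model dim; then
# LayerNorm(Z + FeedForward(Z)).

#' Construct one GRU-attention encoder layer
#'
#' @param model_dim feature dimension of the incoming map (must be divisible
#'   by `heads`).
#' @param heads number of attention heads (default 4).
#' @param gru_hidden hidden size of each head's Q/K/V GRUs per direction
#'   (default `model_dim / heads`).
#' @param ff_mult width multiplier of the feed-forward stage (default 2).
#' @param seed optional RNG seed.
#' @return an `encoder_params` list.
#' @export
encoder_params <- function(model_dim, heads = 4L,
                           gru_hidden = model_dim %/% heads,
                           ff_mult = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (model_dim %% heads != 0L) {
    stop("model_dim (", model_dim, ") must be divisible by heads (", heads, ")")
  }
  hd <- model_dim %/% heads
  p <- list(
    model_dim = as.integer(model_dim), heads = as.integer(heads),
    head_dim = as.integer(hd),
    heads_qkv = lapply(seq_len(heads), function(h) list(
      q = bigru_init(model_dim, gru_hidden, hd),
      k = bigru_init(model_dim, gru_hidden, hd),
      v = bigru_init(model_dim, gru_hidden, hd)
    )),
    conv_a = conv1d_init(3L, model_dim, model_dim),
    conv_b = conv1d_init(3L, model_dim, model_dim),
    reduce = dense_init(model_dim, model_dim),
    ff1 = dense_init(model_dim, ff_mult * model_dim),
    ff2 = dense_init(ff_mult * model_dim, model_dim),
    ln = ln_init(model_dim)
  )
  class(p) <- "encoder_params"
  p
}

#' Forward pass of one encoder layer
#'
#' @param x feature map, `positions x model_dim` matrix or
#'   `[batch, positions, model_dim]` array.
#' @param p an [encoder_params()] object.
#' @param mode `"train"` or `"infer"` (identical here; kept for interface
#'   symmetry with the convolutional stages).
#' @return feature map of identical shape.
#' @export
encoder_layer <- function(x, p, mode = "infer") {
  mat_in <- is.matrix(x)
  if (mat_in) x <- array(x, c(1L, dim(x)))
  out <- encoder_fwd(x, p, mode)$out
  if (mat_in) matrix(out[1, , ], dim(out)[2], dim(out)[3]) else out
}

encoder_fwd <- function(x, p, mode) {
  d <- dim(x); n <- d[1]; L <- d[2]
  heads_out <- array(0, c(n, L, p$model_dim))
  hc <- vector("list", p$heads)
  for (h in seq_len(p$heads)) {
    hp <- p$heads_qkv[[h]]
    q <- bigru_fwd(x, hp$q)
    k <- bigru_fwd(x, hp$k)
    v <- bigru_fwd(x, hp$v)
    a <- attn_fwd(q$out, k$out, v$out, p$head_dim)
    cols <- (h - 1L) * p$head_dim + seq_len(p$head_dim)
    heads_out[, , cols] <- a$out
    hc[[h]] <- list(q = q, k = k, v = v, a = a)
  }
  ca <- conv1d_fwd(heads_out, p$conv_a, 3L)
  cb <- conv1d_fwd(heads_out, p$conv_b, 3L)
  csum <- ca$out + cb$out
  red <- dense_fwd(as_mat(csum), p$reduce)
  Z <- red$out                       # [n*L, model_dim]
  f1 <- dense_fwd(Z, p$ff1)
  r1 <- relu_fwd(f1$out)
  f2 <- dense_fwd(r1$out, p$ff2)
  pre <- as_arr(Z + f2$out, n, L)
  lnr <- ln_fwd(pre, p$ln)
  list(out = lnr$out,
       cache = list(hc = hc, ca = ca, cb = cb, red = red, f1 = f1, r1 = r1,
                    f2 = f2, lnr = lnr, n = n, L = L))
}

encoder_bwd <- function(cache, p, dout) {
  n <- cache$n; L <- cache$L
  g <- list()
  lb <- ln_bwd(cache$lnr$cache, p$ln, dout)
  g$ln <- lb[c("gamma", "beta")]
  dpre <- as_mat(lb$dx)
  f2b <- dense_bwd(cache$f2$cache, p$ff2, dpre)
  g$ff2 <- f2b[c("W", "b")]
  dr1 <- relu_bwd(cache$r1$cache, f2b$dx)
  f1b <- dense_bwd(cache$f1$cache, p$ff1, dr1)
  g$ff1 <- f1b[c("W", "b")]
  dZ <- dpre + f1b$dx
  rb <- dense_bwd(cache$red$cache, p$reduce, dZ)
  g$reduce <- rb[c("W", "b")]
  dcsum <- as_arr(rb$dx, n, L)
  cab <- conv1d_bwd(cache$ca$cache, p$conv_a, dcsum)
  cbb <- conv1d_bwd(cache$cb$cache, p$conv_b, dcsum)
  g$conv_a <- cab[c("W", "b")]
  g$conv_b <- cbb[c("W", "b")]
  dheads <- cab$dx + cbb$dx
  dx <- array(0, c(n, L, p$model_dim))
  g$heads_qkv <- vector("list", p$heads)
  for (h in seq_len(p$heads)) {
    hcache <- cache$hc[[h]]
    cols <- (h - 1L) * p$head_dim + seq_len(p$head_dim)
    dha <- dheads[, , cols, drop = FALSE]
    ab <- attn_bwd(hcache$a$cache, dha)
    qb <- bigru_bwd(hcache$q$cache, p$heads_qkv[[h]]$q, ab$dQ)
    kb <- bigru_bwd(hcache$k$cache, p$heads_qkv[[h]]$k, ab$dK)
    vb <- bigru_bwd(hcache$v$cache, p$heads_qkv[[h]]$v, ab$dV)
    dx <- dx + qb$dx + kb$dx + vb$dx
    g$heads_qkv[[h]] <- list(q = qb[c("fwd", "bwd", "W", "V", "b")],
                             k = kb[c("fwd", "bwd", "W", "V", "b")],
                             v = vb[c("fwd", "bwd", "W", "V", "b")])
  }
  list(dx = dx, grads = g)
}

#' Apply a stack of encoder layers in series
#'
#' @param x feature map (matrix or `[batch, positions, model_dim]` array).
#' @param params list of [encoder_params()] (default depth 4).
#' @param mode `"train"` or `"infer"`.
#' @return feature map after the serial composition.
#' @export
encoder_stack <- function(x, params, mode = "infer") {
  if (inherits(params, "encoder_params")) params <- list(params)
  if (length(params) < 1L) stop("need at least one encoder layer")
  for (p in params) x <- encoder_layer(x, p, mode)
  x
}
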