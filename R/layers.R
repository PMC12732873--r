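# Internal neural-network primitives.
#
# Feature maps are numeric arrays [batch, positions, channels]. Every *_fwd
# returns list(out, cache); the matching *_bwd takes (cache, dout) and
# returns the input gradient plus parameter gradients. Parameter containers
# are plain named lists so the whole model can be flattened for Adam and for
# finite-difference gradient checks.

as_mat <- function(a) matrix(a, dim(a)[1] * dim(a)[2], dim(a)[3])
as_arr <- function(m, n, L) array(m, c(n, L, ncol(m)))

init_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

# ---- 1-D convolution ("same" zero padding) --------------------------------

conv1d_init <- function(k, cin, cout) {
  list(W = init_mat(k * cin, cout, sqrt(2 / (k * cin))), b = numeric(cout))
}

conv1d_fwd <- function(x, p, k) {
  d <- dim(x); n <- d[1]; L <- d[2]; cin <- d[3]
  if (L < k) stop("sequence axis (", L, ") shorter than kernel size ", k)
  pl <- (k - 1L) %/% 2L
  xp <- array(0, c(n, L + k - 1L, cin))
  xp[, pl + seq_len(L), ] <- x
  xcol <- array(0, c(n, L, k * cin))
  for (j in seq_len(k)) {
    xcol[, , ((j - 1L) * cin + 1L):(j * cin)] <- xp[, j:(j + L - 1L), , drop = FALSE]
  }
  xm <- as_mat(xcol)
  out <- sweep(xm %*% p$W, 2, p$b, `+`)
  list(out = as_arr(out, n, L), cache = list(xm = xm, n = n, L = L,
                                             cin = cin, k = k, pl = pl))
}

conv1d_bwd <- function(cache, p, dout) {
  n <- cache$n; L <- cache$L; cin <- cache$cin; k <- cache$k
  dm <- as_mat(dout)
  dW <- crossprod(cache$xm, dm)
  db <- colSums(dm)
  dxcol <- as_arr(dm %*% t(p$W), n, L)
  dxp <- array(0, c(n, L + k - 1L, cin))
  for (j in seq_len(k)) {
    dxp[, j:(j + L - 1L), ] <- dxp[, j:(j + L - 1L), , drop = FALSE] +
      dxcol[, , ((j - 1L) * cin + 1L):(j * cin), drop = FALSE]
  }
  dx <- dxp[, cache$pl + seq_len(L), , drop = FALSE]
  list(dx = dx, W = dW, b = db)
}

# ---- batch normalization (per channel over batch x positions) -------------

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c))
}
bn_state_init <- function(c) list(mean = rep(0, c), var = rep(1, c))

bn_fwd <- function(x, p, state, mode, momentum = 0.9, eps = 1e-5) {
  d <- dim(x); n <- d[1]; L <- d[2]
  xm <- as_mat(x)
  if (mode == "train") {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * va
  } else {
    mu <- state$mean
    va <- state$var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, istd, `*`)
  out <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
  list(out = as_arr(out, n, L),
       cache = list(xhat = xhat, istd = istd, n = n, L = L, mode = mode),
       state = state)
}

bn_bwd <- function(cache, p, dout) {
  dm <- as_mat(dout)
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2, p$gamma, `*`)
  if (cache$mode == "train") {
    N <- nrow(dm)
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
    dxm <- sweep(t1 - t2, 2, cache$istd, `*`)
  } else {
    dxm <- sweep(dxhat, 2, cache$istd, `*`)
  }
  list(dx = as_arr(dxm, cache$n, cache$L), gamma = dgamma, beta = dbeta)
}

# ---- elementwise and pooling ----------------------------------------------

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(cache, dout) dout * cache

# max pool, window 2 stride 2 along positions; odd tails keep the lone element
maxpool_fwd <- function(x) {
  d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]
  L2 <- (L + 1L) %/% 2L
  odd <- L %% 2L == 1L
  ia <- seq(1L, L, by = 2L)
  ib <- seq(2L, L, by = 2L)
  a <- x[, ia, , drop = FALSE]
  if (odd) {
    b <- array(-Inf, c(n, L2, C))
    b[, seq_len(L2 - 1L), ] <- x[, ib, , drop = FALSE]
  } else {
    b <- x[, ib, , drop = FALSE]
  }
  takea <- a >= b
  list(out = pmax(a, b), cache = list(takea = takea, L = L, odd = odd))
}

maxpool_bwd <- function(cache, dout) {
  d <- dim(dout); n <- d[1]; L2 <- d[2]; C <- d[3]
  dx <- array(0, c(n, cache$L, C))
  da <- dout * cache$takea
  db <- dout * !cache$takea
  dx[, seq(1L, cache$L, 2L), ] <- da
  if (cache$odd) {
    if (L2 > 1L) dx[, seq(2L, cache$L, 2L), ] <- db[, seq_len(L2 - 1L), , drop = FALSE]
  } else {
    dx[, seq(2L, cache$L, 2L), ] <- db
  }
  dx
}

# ---- dense / dropout / layer norm -----------------------------------------

dense_init <- function(din, dout) {
  list(W = init_mat(din, dout, sqrt(2 / din)), b = numeric(dout))
}
dense_fwd <- function(x, p) {
  list(out = sweep(x %*% p$W, 2, p$b, `+`), cache = x)
}
dense_bwd <- function(cache, p, dout) {
  list(dx = dout %*% t(p$W), W = crossprod(cache, dout), b = colSums(dout))
}

dropout_fwd <- function(x, rate, mode) {
  if (mode != "train" || rate <= 0) return(list(out = x, cache = NULL))
  mask <- array(stats::runif(length(x)) >= rate, dim(x)) / (1 - rate)
  list(out = x * mask, cache = mask)
}
dropout_bwd <- function(cache, dout) if (is.null(cache)) dout else dout * cache

ln_init <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

# normalizes each row (one position's feature vector) to zero mean, unit var
ln_fwd <- function(x, p, eps = 1e-5) {
  d <- dim(x); n <- d[1]; L <- d[2]
  xm <- as_mat(x)
  mu <- rowMeans(xm)
  va <- rowMeans(xm^2) - mu^2
  istd <- 1 / sqrt(va + eps)
  xhat <- (xm - mu) * istd
  out <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
  list(out = as_arr(out, n, L),
       cache = list(xhat = xhat, istd = istd, n = n, L = L))
}

ln_bwd <- function(cache, p, dout) {
  dm <- as_mat(dout)
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2, p$gamma, `*`)
  Cn <- ncol(dm)
  dxm <- (dxhat - rowMeans(dxhat) -
            cache$xhat * rowMeans(dxhat * cache$xhat)) * cache$istd
  list(dx = as_arr(dxm, cache$n, cache$L), gamma = dgamma, beta = dbeta)
}

# ---- row softmax -----------------------------------------------------------

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}
softmax_rows_bwd <- function(A, dA) A * (dA - rowSums(dA * A))

# ---- global pooling head ---------------------------------------------------

# parallel pooling: global max || global mean over the position axis
gpool_fwd <- function(x) {
  d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]
  mx <- apply(x, c(1, 3), max)
  am <- apply(x, c(1, 3), which.max)
  av <- apply(x, c(1, 3), mean)
  list(out = cbind(mx, av), cache = list(argmax = am, n = n, L = L, C = C))
}

gpool_bwd <- function(cache, dout) {
  n <- cache$n; L <- cache$L; C <- cache$C
  dmx <- dout[, seq_len(C), drop = FALSE]
  dav <- dout[, C + seq_len(C), drop = FALSE]
  dx <- array(rep(dav / L, each = 1), c(n, C, L))   # fill then fix max part
  dx <- aperm(dx, c(1, 3, 2))
  idx <- cbind(rep(seq_len(n), C),
               as.vector(cache$argmax),
               rep(seq_len(C), each = n))
  dx[idx] <- dx[idx] + as.vector(dmx)
  dx
}
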