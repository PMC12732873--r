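# Gated recurrent units (forward + backward-through-time), used to build the
# query/key/value projections of the attention encoder and the trailing
# context stage. Gate order in the packed weight matrices is [update z,
# reset r, candidate c]; the state recurrence follows
#   h_t = z_t * h_{t-1} + (1 - z_t) * hcand_t
# so forcing z to 1 freezes the state and forcing z to 0 passes the
# candidate through unchanged.

gru_cell_init <- function(din, h) {
  s <- sqrt(1 / h)
  list(Wx = init_mat(din, 3L * h, sqrt(1 / din)),
       Wh = init_mat(h, 3L * h, s),
       b = numeric(3L * h))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# x: [n, L, din]; returns hidden states [n, L, h] plus per-step caches
gru_cell_fwd <- function(x, p, reverse = FALSE) {
  d <- dim(x); n <- d[1]; L <- d[2]
  h <- ncol(p$Wh)
  hdim <- h %/% 3L
  iz <- seq_len(hdim); ir <- hdim + iz; ic <- 2L * hdim + iz
  steps <- if (reverse) rev(seq_len(L)) else seq_len(L)
  hs <- array(0, c(n, L, hdim))
  hprev <- matrix(0, n, hdim)
  cache <- vector("list", L)
  xW <- as_mat(x) %*% p$Wx          # precompute input projections
  for (s in seq_along(steps)) {
    t <- steps[s]
    rows <- (seq_len(n)) + (t - 1L) * n
    ax <- xW[rows, , drop = FALSE]
    ah <- hprev %*% p$Wh
    z <- sigmoid(ax[, iz, drop = FALSE] + ah[, iz, drop = FALSE] + rep(p$b[iz], each = n))
    r <- sigmoid(ax[, ir, drop = FALSE] + ah[, ir, drop = FALSE] + rep(p$b[ir], each = n))
    rh <- r * hprev
    hc <- tanh(ax[, ic, drop = FALSE] + rh %*% p$Wh[, ic, drop = FALSE] + rep(p$b[ic], each = n))
    hnew <- z * hprev + (1 - z) * hc
    hs[, t, ] <- hnew
    cache[[s]] <- list(t = t, z = z, r = r, hc = hc, hprev = hprev, rh = rh)
    hprev <- hnew
  }
  list(out = hs, cache = list(steps = cache, x = x, n = n, L = L,
                              hdim = hdim, reverse = reverse))
}

gru_cell_bwd <- function(cache, p, dout) {
  n <- cache$n; L <- cache$L; hdim <- cache$hdim
  iz <- seq_len(hdim); ir <- hdim + iz; ic <- 2L * hdim + iz
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dWh <- matrix(0, hdim, 3L * hdim)
  db <- numeric(3L * hdim)
  dxW <- matrix(0, n * L, 3L * hdim)
  dh <- matrix(0, n, hdim)
  for (s in rev(seq_len(L))) {
    st <- cache$steps[[s]]
    t <- st$t
    dh <- dh + matrix(dout[, t, ], n, hdim)
    dz <- dh * (st$hprev - st$hc)
    dhc <- dh * (1 - st$z)
    dhprev <- dh * st$z
    dac <- dhc * (1 - st$hc^2)
    drh <- dac %*% t(p$Wh[, ic, drop = FALSE])
    dr <- drh * st$hprev
    dhprev <- dhprev + drh * st$r
    daz <- dz * st$z * (1 - st$z)
    dar <- dr * st$r * (1 - st$r)
    dhprev <- dhprev + daz %*% t(p$Wh[, iz, drop = FALSE]) +
      dar %*% t(p$Wh[, ir, drop = FALSE])
    da <- cbind(daz, dar, dac)
    rows <- seq_len(n) + (t - 1L) * n
    dxW[rows, ] <- da
    dWh[, iz] <- dWh[, iz] + crossprod(st$hprev, daz)
    dWh[, ir] <- dWh[, ir] + crossprod(st$hprev, dar)
    dWh[, ic] <- dWh[, ic] + crossprod(st$rh, dac)
    db <- db + colSums(da)
    dh <- dhprev
  }
  xm <- as_mat(cache$x)
  dWx <- crossprod(xm, dxW)
  dx <- as_arr(dxW %*% t(p$Wx), n, L)
  list(dx = dx, Wx = dWx, Wh = dWh, b = db)
}

# ---- bidirectional GRU with learned linear combination --------------------
# h_t = fh_t W + bh_t V + b, the head-projection form used throughout the
# encoder (forward and backward passes combined position-wise).

bigru_init <- function(din, hidden, dout) {
  list(fwd = gru_cell_init(din, hidden),
       bwd = gru_cell_init(din, hidden),
       W = init_mat(hidden, dout, sqrt(1 / hidden)),
       V = init_mat(hidden, dout, sqrt(1 / hidden)),
       b = numeric(dout))
}

bigru_fwd <- function(x, p) {
  f <- gru_cell_fwd(x, p$fwd, reverse = FALSE)
  b <- gru_cell_fwd(x, p$bwd, reverse = TRUE)
  n <- dim(x)[1]; L <- dim(x)[2]
  fm <- as_mat(f$out); bm <- as_mat(b$out)
  out <- sweep(fm %*% p$W + bm %*% p$V, 2, p$b, `+`)
  list(out = as_arr(out, n, L),
       cache = list(f = f, b = b, fm = fm, bm = bm, n = n, L = L))
}

bigru_bwd <- function(cache, p, dout) {
  dm <- as_mat(dout)
  dW <- crossprod(cache$fm, dm)
  dV <- crossprod(cache$bm, dm)
  db <- colSums(dm)
  dfh <- as_arr(dm %*% t(p$W), cache$n, cache$L)
  dbh <- as_arr(dm %*% t(p$V), cache$n, cache$L)
  gf <- gru_cell_bwd(cache$f$cache, p$fwd, dfh)
  gb <- gru_cell_bwd(cache$b$cache, p$bwd, dbh)
  list(dx = gf$dx + gb$dx,
       fwd = gf[c("Wx", "Wh", "b")],
       bwd = gb[c("Wx", "Wh", "b")],
       W = dW, V = dV, b = db)
}

#' Run a gated-recurrent-unit sequence pass
#'
#' Applies a GRU along the position axis of a feature map. The recurrence is
#' `h_t = z_t * h_(t-1) + (1 - z_t) * hcand_t` with standard sigmoid update
#' and reset gates and a tanh candidate state. In bidirectional mode the
#' forward and backward hidden sequences are combined position-wise through a
#' learned linear map `fh_t W + bh_t V + b`.
#'
#' @param x feature map: a `positions x features` matrix or a
#'   `[batch, positions, features]` array.
#' @param p parameters from `gru_cell_init()` (uni-directional) or
#'   `bigru_init()` (bidirectional); see [gru_params()].
#' @param direction `"forward"`, `"backward"` or `"bidirectional"`.
#' @return hidden-state feature map with the same positions axis.
#' @export
gru_sequence <- function(x, p, direction = c("forward", "backward",
                                             "bidirectional")) {
  direction <- match.arg(direction)
  mat_in <- is.matrix(x)
  if (mat_in) x <- array(x, c(1L, nrow(x), ncol(x)))
  out <- switch(direction,
    forward = gru_cell_fwd(x, p, reverse = FALSE)$out,
    backward = gru_cell_fwd(x, p, reverse = TRUE)$out,
    bidirectional = bigru_fwd(x, p)$out
  )
  if (mat_in) matrix(out[1, , ], dim(out)[2], dim(out)[3]) else out
}

#' Construct GRU parameters
#'
#' Initializes the weights of a uni- or bidirectional GRU for use with
#' [gru_sequence()]. Packed gate order in the weight matrices is update,
#' reset, candidate.
#'
#' @param input_dim input feature count.
#' @param hidden_dim hidden-state size per direction.
#' @param output_dim combined output size (bidirectional only).
#' @param bidirectional build forward and backward cells plus the linear
#'   combination weights.
#' @param seed optional RNG seed for reproducible initialization.
#' @return a named parameter list.
#' @export
gru_params <- function(input_dim, hidden_dim, output_dim = hidden_dim,
                       bidirectional = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (bidirectional) bigru_init(input_dim, hidden_dim, output_dim)
  else gru_cell_init(input_dim, hidden_dim)
}
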