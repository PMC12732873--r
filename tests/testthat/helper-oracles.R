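# Independent reference implementations used as oracles. These are written
# as plain nested loops / textbook recursions, deliberately sharing no code
# with the package internals.

# Cox-de Boor recursion, one basis function at a time (recursive form)
naive_bspline <- function(x, knots, i, k) {
  if (k == 0) {
    last <- i == length(knots) - 1
    if ((x >= knots[i] && x < knots[i + 1]) ||
        (last && x >= knots[i] && x <= knots[i + 1])) 1 else 0
  } else {
    d1 <- knots[i + k] - knots[i]
    d2 <- knots[i + k + 1] - knots[i + 1]
    t1 <- if (d1 > 0) (x - knots[i]) / d1 *
        naive_bspline(x, knots, i, k - 1) else 0
    t2 <- if (d2 > 0) (knots[i + k + 1] - x) / d2 *
        naive_bspline(x, knots, i + 1, k - 1) else 0
    t1 + t2
  }
}
naive_bspline_row <- function(x, knots, k) {
  nb <- length(knots) - 1 - k
  vapply(seq_len(nb), function(i) naive_bspline(x, knots, i, k), 0)
}

# Eq-2-style KANLinear evaluation by triple loop
naive_kan_forward <- function(x, layer) {
  nb <- layer$n_basis
  out <- numeric(layer$out_dim)
  for (o in seq_len(layer$out_dim)) {
    acc <- 0
    for (c in seq_len(layer$in_dim)) {
      acc <- acc + x[c] * layer$base_weight[c, o]
      knots <- promkan:::extend_knots(layer$grid[c, ], layer$degree)
      bases <- naive_bspline_row(x[c], knots, layer$degree)
      for (b in seq_len(nb)) {
        acc <- acc + bases[b] * layer$spline_weight[(c - 1) * nb + b, o]
      }
    }
    out[o] <- acc
  }
  out
}

# sliding-window same-padded 1-D convolution, nested loops
naive_conv1d <- function(x, W, b, k) {
  # x: L x Cin matrix; W: (k*Cin) x Cout with row order (offset-major)
  L <- nrow(x); cin <- ncol(x); cout <- ncol(W)
  pl <- (k - 1) %/% 2
  out <- matrix(0, L, cout)
  for (pos in seq_len(L)) {
    for (o in seq_len(cout)) {
      acc <- b[o]
      for (j in seq_len(k)) {
        src <- pos + j - 1 - pl
        if (src >= 1 && src <= L) {
          for (c in seq_len(cin)) {
            acc <- acc + x[src, c] * W[(j - 1) * cin + c, o]
          }
        }
      }
      out[pos, o] <- acc
    }
  }
  out
}

# per-unit unrolled GRU recurrence
naive_gru <- function(x, p) {
  # x: L x din; gate order [update, reset, candidate]
  L <- nrow(x)
  h <- ncol(p$Wh) / 3
  iz <- 1:h; ir <- h + iz; ic <- 2 * h + iz
  hs <- matrix(0, L, h)
  hprev <- numeric(h)
  sig <- function(v) 1 / (1 + exp(-v))
  for (t in seq_len(L)) {
    a <- drop(x[t, ] %*% p$Wx) + drop(hprev %*% p$Wh) + p$b
    z <- sig(a[iz])
    r <- sig(a[ir])
    ac <- drop(x[t, ] %*% p$Wx[, ic]) + drop((r * hprev) %*% p$Wh[, ic]) + p$b[ic]
    hc <- tanh(ac)
    hprev <- z * hprev + (1 - z) * hc
    hs[t, ] <- hprev
  }
  hs
}

# double-loop attention: scores, softmax, weighted sum
naive_attention <- function(Q, K, V, dK) {
  L <- nrow(Q)
  out <- matrix(0, L, ncol(V))
  for (i in seq_len(L)) {
    s <- numeric(L)
    for (j in seq_len(L)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dK)
    w <- exp(s - max(s)); w <- w / sum(w)
    for (j in seq_len(L)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# type-7 quantile by hand (linear interpolation between order statistics)
naive_quantile7 <- function(v, p) {
  s <- sort(v); n <- length(s)
  vapply(p, function(pp) {
    h <- (n - 1) * pp
    lo <- floor(h) + 1
    if (lo >= n) s[n] else s[lo] + (h - lo + 1) * (s[lo + 1] - s[lo])
  }, 0)
}

# literal confusion-matrix formulas
naive_metrics <- function(TP, TN, FP, FN) {
  list(Sn = TP / (TP + FN), Sp = TN / (TN + FP),
       Acc = (TP + TN) / (TP + TN + FP + FN),
       MCC = (TP * TN - FP * FN) /
         sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)))
}

# small configurations used across tests to keep runtimes short
tiny_config <- function(max_epochs = 2L, seq_length = 30L, ...) {
  promkan_config(seq_length = seq_length, branch_kernels = c(3L, 5L),
                 branch_filters = c(3L, 3L), trunk_channels = 4L,
                 kresidual_blocks = 1L, encoder_count = 1L, heads = 2L,
                 gru_hidden = 2L, ff_mult = 1L, dropout_rate = 0,
                 batch_size = 10L, max_epochs = max_epochs, ...)
}

tiny_dataset <- function(n_per_class = 15L, seed = 1L, mutation_rate = 0) {
  simulate_promoters(n_per_class, seq_length = 30L, motif_position = 11L,
                     mutation_rate = mutation_rate, seed = seed)
}

random_seq <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
}
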