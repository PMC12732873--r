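#' Model configuration
#'
#' Collects every architectural and training hyperparameter of the
#' promoter classifier. Defaults give the full-size architecture: input
#' length 81 nt, four parallel convolution branches (kernels 3/5/7/9,
#' filters 32/48/64/80), a 128-channel trunk, 4 KRAN residual blocks,
#' 4 GRU-attention encoder layers with 4 heads, batch size 30, Adam with
#' learning rate 1e-3, dropout 0.5 before the dense head, and the
#' regularized label-smoothing loss (epsilon 0.1, lambda 1e-4).
#'
#' @param seq_length input sequence length (nt).
#' @param branch_kernels,branch_filters kernel sizes and filter counts of
#'   the parallel convolution branches.
#' @param trunk_channels channel width after the compressing convolution;
#'   also the model dimension of the residual and encoder stages.
#' @param kresidual_blocks number of KRAN blocks stacked in series.
#' @param encoder_count number of encoder layers stacked in series.
#' @param heads attention heads per encoder layer (must divide
#'   `trunk_channels`).
#' @param gru_hidden hidden size per direction of the Q/K/V GRUs (default
#'   `trunk_channels / heads`).
#' @param ff_mult feed-forward width multiplier inside each encoder layer.
#' @param spline_grid_size,spline_degree B-spline grid intervals and degree
#'   of every KANLinear layer (defaults 5 and 3).
#' @param grid_mix_uniform uniform-grid weight of the adaptive knot update.
#' @param adaptive_grid enable the per-batch knot update during training
#'   (default `FALSE`: the update destabilizes convergence at small batch
#'   sizes, so the knots stay at their initial uniform positions).
#' @param batch_size minibatch size (default 30).
#' @param learning_rate Adam step size.
#' @param max_epochs epoch budget.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping (default 10).
#' @param min_delta minimum improvement that resets patience.
#' @param dropout_rate dropout before the dense head.
#' @param epsilon label-smoothing factor of the loss.
#' @param lambda probability-norm regularization coefficient of the loss.
#' @param val_fraction fraction of training data held out for early
#'   stopping.
#' @param threshold classification threshold on the output probability.
#' @return a `promkan_config` list.
#' @export
promkan_config <- function(seq_length = 81L,
                           branch_kernels = c(3L, 5L, 7L, 9L),
                           branch_filters = c(32L, 48L, 64L, 80L),
                           trunk_channels = 128L,
                           kresidual_blocks = 4L,
                           encoder_count = 4L,
                           heads = 4L,
                           gru_hidden = NULL,
                           ff_mult = 2L,
                           spline_grid_size = 5L,
                           spline_degree = 3L,
                           grid_mix_uniform = 0.02,
                           adaptive_grid = FALSE,
                           batch_size = 30L,
                           learning_rate = 1e-3,
                           max_epochs = 100L,
                           early_stop_patience = 10L,
                           min_delta = 1e-4,
                           dropout_rate = 0.5,
                           epsilon = 0.1,
                           lambda = 1e-4,
                           val_fraction = 0.2,
                           threshold = 0.5) {
  if (is.null(gru_hidden)) gru_hidden <- max(1L, trunk_channels %/% heads)
  cfg <- list(seq_length = as.integer(seq_length),
              branch_kernels = as.integer(branch_kernels),
              branch_filters = as.integer(branch_filters),
              trunk_channels = as.integer(trunk_channels),
              kresidual_blocks = as.integer(kresidual_blocks),
              encoder_count = as.integer(encoder_count),
              heads = as.integer(heads),
              gru_hidden = as.integer(gru_hidden),
              ff_mult = as.integer(ff_mult),
              spline_grid_size = as.integer(spline_grid_size),
              spline_degree = as.integer(spline_degree),
              grid_mix_uniform = grid_mix_uniform,
              adaptive_grid = isTRUE(adaptive_grid),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              max_epochs = as.integer(max_epochs),
              early_stop_patience = as.integer(early_stop_patience),
              min_delta = min_delta,
              dropout_rate = dropout_rate,
              epsilon = epsilon,
              lambda = lambda,
              val_fraction = val_fraction,
              threshold = threshold)
  stopifnot(cfg$seq_length > 0, cfg$kresidual_blocks > 0,
            cfg$encoder_count > 0, cfg$heads > 0, cfg$batch_size > 0,
            cfg$dropout_rate >= 0, cfg$dropout_rate < 1,
            length(cfg$branch_kernels) == length(cfg$branch_filters))
  if (cfg$trunk_channels %% cfg$heads != 0L) {
    stop("trunk_channels must be divisible by heads")
  }
  class(cfg) <- "promkan_config"
  cfg
}

#' Assemble an untrained model
#'
#' Initializes every parameter tensor of the classifier: hybrid-encoded
#' input -> multi-scale convolution front end -> serial KRAN blocks ->
#' GRU-attention encoder stack -> trailing bidirectional GRU -> parallel
#' (max || mean) global pooling -> dropout -> dense sigmoid output.
#'
#' @param config a [promkan_config()].
#' @param stage which classification stage the model is for: 1 (promoter vs
#'   non-promoter) or 2 (strong vs weak).
#' @param seed RNG seed for weight initialization.
#' @return an untrained object of class `promkan`.
#' @export
promkan_build <- function(config = promkan_config(), stage = 1L, seed = 1L) {
  stopifnot(stage %in% c(1L, 2L))
  set.seed(seed)
  C <- config$trunk_channels
  params <- list(
    ms = multiscale_params(7L, config$branch_kernels, config$branch_filters, C),
    blocks = lapply(seq_len(config$kresidual_blocks), function(i) {
      b <- kran_block_params(C, config$spline_grid_size, config$spline_degree)
      b$kan$grid_mix_uniform <- config$grid_mix_uniform
      b$kan$adaptive_update <- config$adaptive_grid
      b
    }),
    encoders = lapply(seq_len(config$encoder_count), function(i) {
      encoder_params(C, heads = config$heads, gru_hidden = config$gru_hidden,
                     ff_mult = config$ff_mult)
    }),
    tail = bigru_init(C, max(1L, C %/% 2L), C),
    head = dense_init(2L * C, 1L)
  )
  structure(list(config = config, stage = as.integer(stage), params = params,
                 history = NULL, trained = FALSE, seed = as.integer(seed)),
            class = "promkan")
}

# ---- full forward / backward ----------------------------------------------

model_fwd <- function(params, x, mode, config, drop_seeded = TRUE) {
  ms <- multiscale_fwd(x, params$ms, mode)
  h <- ms$out
  bc <- vector("list", length(params$blocks))
  for (i in seq_along(params$blocks)) {
    bc[[i]] <- kran_fwd(h, params$blocks[[i]], mode)
    h <- bc[[i]]$out
  }
  ec <- vector("list", length(params$encoders))
  for (i in seq_along(params$encoders)) {
    ec[[i]] <- encoder_fwd(h, params$encoders[[i]], mode)
    h <- ec[[i]]$out
  }
  tl <- bigru_fwd(h, params$tail)
  gp <- gpool_fwd(tl$out)
  dp <- dropout_fwd(gp$out, config$dropout_rate, mode)
  hd <- dense_fwd(dp$out, params$head)
  prob <- as.vector(sigmoid(hd$out))
  list(prob = prob,
       cache = list(ms = ms, bc = bc, ec = ec, tl = tl, gp = gp, dp = dp,
                    hd = hd),
       states = list(ms_bn = ms$state,
                     blocks = lapply(bc, `[[`, "state")),
       kan_inputs = lapply(bc, `[[`, "kan_input"))
}

model_bwd <- function(params, cache, dprob_dscore) {
  g <- list()
  hb <- dense_bwd(cache$hd$cache, params$head, matrix(dprob_dscore, ncol = 1L))
  g$head <- hb[c("W", "b")]
  ddp <- dropout_bwd(cache$dp$cache, hb$dx)
  dgp <- gpool_bwd(cache$gp$cache, ddp)
  tb <- bigru_bwd(cache$tl$cache, params$tail, dgp)
  g$tail <- tb[c("fwd", "bwd", "W", "V", "b")]
  dh <- tb$dx
  g$encoders <- vector("list", length(params$encoders))
  for (i in rev(seq_along(params$encoders))) {
    eb <- encoder_bwd(cache$ec[[i]]$cache, params$encoders[[i]], dh)
    g$encoders[[i]] <- eb$grads
    dh <- eb$dx
  }
  g$blocks <- vector("list", length(params$blocks))
  for (i in rev(seq_along(params$blocks))) {
    kb <- kran_bwd(cache$bc[[i]]$cache, params$blocks[[i]], dh)
    g$blocks[[i]] <- kb$grads
    dh <- kb$dx
  }
  mb <- multiscale_bwd(cache$ms$cache, params$ms, dh)
  g$ms <- mb$grads
  g
}

# ---- trainable-parameter bookkeeping --------------------------------------
# Extracts the trainable tensors into a nested list whose shape matches the
# gradient lists returned by model_bwd, so both flatten to aligned vectors.

kan_trainable <- function(p) p[c("base_weight", "spline_weight")]

model_trainable <- function(params) {
  list(
    head = params$head,
    tail = params$tail[c("fwd", "bwd", "W", "V", "b")],
    encoders = lapply(params$encoders, function(e) {
      list(heads_qkv = e$heads_qkv, conv_a = e$conv_a, conv_b = e$conv_b,
           reduce = e$reduce, ff1 = e$ff1, ff2 = e$ff2, ln = e$ln)
    }),
    blocks = lapply(params$blocks, function(b) {
      list(main_conv = b$main_conv, main_bn = b$main_bn,
           kan = kan_trainable(b$kan),
           short_conv = b$short_conv, short_bn = b$short_bn)
    }),
    ms = list(branches = params$ms$branches, bn = params$ms$bn,
              trunk = params$ms$trunk)
  )
}

model_grads_aligned <- function(g) {
  list(
    head = g$head,
    tail = g$tail,
    encoders = lapply(g$encoders, function(e) {
      list(heads_qkv = e$heads_qkv, conv_a = e$conv_a, conv_b = e$conv_b,
           reduce = e$reduce, ff1 = e$ff1, ff2 = e$ff2, ln = e$ln)
    }),
    blocks = lapply(g$blocks, function(b) {
      list(main_conv = b$main_conv, main_bn = b$main_bn, kan = b$kan,
           short_conv = b$short_conv, short_bn = b$short_bn)
    }),
    ms = list(branches = g$ms$branches, bn = g$ms$bn, trunk = g$ms$trunk)
  )
}

model_set_trainable <- function(params, v) {
  params$head <- v$head
  params$tail[c("fwd", "bwd", "W", "V", "b")] <- v$tail
  for (i in seq_along(params$encoders)) {
    e <- v$encoders[[i]]
    params$encoders[[i]]$heads_qkv <- e$heads_qkv
    params$encoders[[i]]$conv_a <- e$conv_a
    params$encoders[[i]]$conv_b <- e$conv_b
    params$encoders[[i]]$reduce <- e$reduce
    params$encoders[[i]]$ff1 <- e$ff1
    params$encoders[[i]]$ff2 <- e$ff2
    params$encoders[[i]]$ln <- e$ln
  }
  for (i in seq_along(params$blocks)) {
    b <- v$blocks[[i]]
    params$blocks[[i]]$main_conv <- b$main_conv
    params$blocks[[i]]$main_bn <- b$main_bn
    params$blocks[[i]]$kan$base_weight <- b$kan$base_weight
    params$blocks[[i]]$kan$spline_weight <- b$kan$spline_weight
    params$blocks[[i]]$short_conv <- b$short_conv
    params$blocks[[i]]$short_bn <- b$short_bn
  }
  params$ms$branches <- v$ms$branches
  params$ms$bn <- v$ms$bn
  params$ms$trunk <- v$ms$trunk
  params
}

model_set_states <- function(params, states) {
  params$ms$state <- states$ms_bn
  for (i in seq_along(params$blocks)) {
    params$blocks[[i]]$state <- states$blocks[[i]]
  }
  params
}

model_get_states <- function(params) {
  list(ms_bn = params$ms$state,
       blocks = lapply(params$blocks, `[[`, "state"))
}

# ---- fitting ---------------------------------------------------------------

#' Fit the two-stage promoter classifier (one stage)
#'
#' The main fitting function: builds the model for the requested stage and
#' trains it on the labeled records of `ds` with Adam, minibatch size
#' `config$batch_size`, minimizing the regularized label-smoothing loss.
#' A stratified fraction of the data (`config$val_fraction`) is held out to
#' monitor validation loss; training stops early when it fails to improve
#' by `config$min_delta` for `config$early_stop_patience` epochs, and the
#' best-validation parameters are restored.
#'
#' Stage 1 uses all records with a promoter / non-promoter label (positive
#' class: promoter); stage 2 uses promoter records with a strength label
#' (positive class: strong).
#'
#' @param ds a labeled [promoter_dataset()].
#' @param stage 1 or 2.
#' @param config a [promkan_config()].
#' @param seed seed controlling initialization, data shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return a fitted `promkan` object with a `history` data frame
#'   (epoch, train_loss, val_loss, val_acc).
#' @seealso [predict.promkan()], [predict_two_stage()], [repeated_cv()]
#' @export
promkan <- function(ds, stage = 1L, config = promkan_config(), seed = 1L,
                    verbose = FALSE) {
  model <- promkan_build(config, stage, seed)
  promkan_train(model, ds, verbose = verbose)
}

#' Train (or continue training) a built model
#'
#' @param model a `promkan` object from [promkan_build()].
#' @param ds a labeled [promoter_dataset()].
#' @param verbose print per-epoch losses.
#' @return the trained `promkan` object.
#' @export
promkan_train <- function(model, ds, verbose = FALSE) {
  cfg <- model$config
  y <- stage_labels(ds, model$stage)
  keep <- which(!is.na(y))
  if (length(keep) < 4L) stop("too few labeled records for stage ", model$stage)
  y <- y[keep]
  if (length(unique(y)) < 2L) {
    stop("training requires both classes for stage ", model$stage)
  }
  if (attr(ds, "seq_length") != cfg$seq_length) {
    stop("dataset length ", attr(ds, "seq_length"),
         " does not match config seq_length ", cfg$seq_length)
  }
  X <- encode_dataset(ds[keep, ])
  set.seed(model$seed + 1L)

  # stratified train / validation split
  val_idx <- integer(0)
  for (cl in unique(y)) {
    ci <- which(y == cl)
    nv <- max(1L, floor(length(ci) * cfg$val_fraction))
    val_idx <- c(val_idx, sample(ci, nv))
  }
  tr_idx <- setdiff(seq_along(y), val_idx)

  params <- model$params
  theta <- unlist(model_trainable(params), use.names = FALSE)
  skel <- model_trainable(params)
  m_adam <- v_adam <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  best_val <- Inf; best_theta <- theta; best_states <- model_get_states(params)
  wait <- 0L
  history <- NULL

  eval_set <- function(idx) {
    probs <- forward_in_chunks(params, X[idx, , , drop = FALSE], cfg)
    loss <- reg_smooth_loss(y[idx], probs, cfg$epsilon, cfg$lambda)
    acc <- mean((probs >= cfg$threshold) == (y[idx] == 1))
    c(loss, acc)
  }

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(tr_idx)
    nb <- ceiling(length(ord) / cfg$batch_size)
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      rows <- ord[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size,
                                                        length(ord))]
      xb <- X[rows, , , drop = FALSE]
      yb <- y[rows]
      fw <- model_fwd(params, xb, "train", cfg)
      params <- model_set_states(params, fw$states)
      loss <- reg_smooth_loss(yb, fw$prob, cfg$epsilon, cfg$lambda)
      ep_loss <- ep_loss + loss * length(rows)
      dp <- reg_smooth_grad(yb, fw$prob, cfg$epsilon, cfg$lambda)
      dscore <- dp * fw$prob * (1 - fw$prob)
      g <- model_bwd(params, fw$cache, dscore)
      gvec <- unlist(model_grads_aligned(g), use.names = FALSE)
      step <- step + 1L
      m_adam <- b1 * m_adam + (1 - b1) * gvec
      v_adam <- b2 * v_adam + (1 - b2) * gvec^2
      mhat <- m_adam / (1 - b1^step)
      vhat <- v_adam / (1 - b2^step)
      theta <- theta - cfg$learning_rate * mhat / (sqrt(vhat) + adam_eps)
      params <- model_set_trainable(params, utils::relist(theta, skel))
      if (cfg$adaptive_grid) {
        for (i in seq_along(params$blocks)) {
          params$blocks[[i]]$kan$grid <-
            update_grid(fw$kan_inputs[[i]], params$blocks[[i]]$kan)
        }
      }
    }
    va <- eval_set(val_idx)
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = ep_loss / length(ord),
                                val_loss = va[1], val_acc = va[2]))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  val-acc %.3f",
                      epoch, ep_loss / length(ord), va[1], va[2]))
    }
    if (va[1] < best_val - cfg$min_delta) {
      best_val <- va[1]; best_theta <- theta
      best_states <- model_get_states(params)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) break
    }
  }
  params <- model_set_trainable(params, utils::relist(best_theta, skel))
  params <- model_set_states(params, best_states)
  model$params <- params
  model$history <- history
  model$trained <- TRUE
  model
}

# inference in memory-bounded chunks
forward_in_chunks <- function(params, X, cfg, chunk = 64L) {
  n <- dim(X)[1]
  probs <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    probs[s:e] <- model_fwd(params, X[s:e, , , drop = FALSE], "infer", cfg)$prob
  }
  probs
}

# ---- prediction and methods -----------------------------------------------

#' Predict from a fitted promoter model
#'
#' @param object a `promkan` model.
#' @param newdata a [promoter_dataset()] or character vector of sequences.
#' @param type `"prob"` for positive-class probabilities (stage 1:
#'   promoter; stage 2: strong), `"class"` for thresholded labels.
#' @param ... unused.
#' @return numeric probabilities or a character label vector.
#' @export
predict.promkan <- function(object, newdata,
                            type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- encode_dataset(newdata)
  if (dim(X)[2] != object$config$seq_length) {
    stop("sequence length ", dim(X)[2], " does not match the model (",
         object$config$seq_length, ")")
  }
  probs <- forward_in_chunks(object$params, X, object$config)
  if (type == "prob") return(probs)
  pos <- if (object$stage == 1L) "promoter" else "strong"
  neg <- if (object$stage == 1L) "non_promoter" else "weak"
  ifelse(probs >= object$config$threshold, pos, neg)
}

#' Two-stage promoter prediction
#'
#' Routes every sequence through the hierarchy: the stage-1 model calls
#' promoter vs non-promoter; sequences called promoter are passed to the
#' stage-2 model for a strong / weak call, all others get no strength label.
#'
#' @param m1 fitted stage-1 `promkan` model.
#' @param m2 fitted stage-2 `promkan` model.
#' @param ds a [promoter_dataset()] (labels not required).
#' @param threshold stage-1 and stage-2 probability threshold (default from
#'   the stage-1 config).
#' @return data frame: `id`, `stage1_prob`, `stage1_label`, `stage2_prob`,
#'   `stage2_label` (`NA` for non-promoter calls).
#' @export
predict_two_stage <- function(m1, m2, ds, threshold = NULL) {
  if (m1$stage != 1L || m2$stage != 2L) {
    stop("m1 must be a stage-1 model and m2 a stage-2 model")
  }
  if (is.null(threshold)) threshold <- m1$config$threshold
  p1 <- predict(m1, ds, type = "prob")
  is_prom <- p1 >= threshold
  p2 <- rep(NA_real_, nrow(ds))
  s2 <- rep(NA_character_, nrow(ds))
  if (any(is_prom)) {
    p2[is_prom] <- predict(m2, ds[is_prom, ], type = "prob")
    s2[is_prom] <- ifelse(p2[is_prom] >= threshold, "strong", "weak")
  }
  data.frame(id = ds$id,
             stage1_prob = p1,
             stage1_label = ifelse(is_prom, "promoter", "non_promoter"),
             stage2_prob = p2,
             stage2_label = s2,
             stringsAsFactors = FALSE)
}

#' @export
print.promkan <- function(x, ...) {
  cat(sprintf("promkan stage-%d model (%s)\n", x$stage,
              if (x$trained) "trained" else "untrained"))
  cat(sprintf("  %d KRAN blocks | %d encoder layers x %d heads | %d trunk channels\n",
              x$config$kresidual_blocks, x$config$encoder_count,
              x$config$heads, x$config$trunk_channels))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  %d epochs, final val loss %.4f, val acc %.3f\n",
                nrow(x$history), last$val_loss, last$val_acc))
  }
  invisible(x)
}

#' Architecture and training summary
#'
#' @param object a `promkan` model.
#' @param ... unused.
#' @return a `summary.promkan` list reporting the instantiated architecture
#'   (block / encoder / head counts, channel widths, batch size, input
#'   length, parameter count) and training history if present.
#' @export
summary.promkan <- function(object, ...) {
  n_par <- length(unlist(model_trainable(object$params), use.names = FALSE))
  out <- list(stage = object$stage,
              seq_length = object$config$seq_length,
              kresidual_blocks = length(object$params$blocks),
              encoder_count = length(object$params$encoders),
              heads = object$params$encoders[[1]]$heads,
              trunk_channels = object$config$trunk_channels,
              batch_size = object$config$batch_size,
              dropout_rate = object$config$dropout_rate,
              n_parameters = n_par,
              trained = object$trained,
              history = object$history)
  class(out) <- "summary.promkan"
  out
}

#' @export
print.summary.promkan <- function(x, ...) {
  cat(sprintf("stage-%d promoter classifier\n", x$stage))
  cat(sprintf("  input length: %d nt (hybrid one-hot + NCP, 7 channels)\n",
              x$seq_length))
  cat(sprintf("  KRAN blocks: %d   encoders: %d   heads: %d   trunk: %d ch\n",
              x$kresidual_blocks, x$encoder_count, x$heads, x$trunk_channels))
  cat(sprintf("  batch size: %d   dropout: %.2f   parameters: %d\n",
              x$batch_size, x$dropout_rate, x$n_parameters))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs, best val loss %.4f\n",
                nrow(x$history), min(x$history$val_loss)))
  }
  invisible(x)
}

#' @export
plot.promkan <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", col = "steelblue",
                 xlab = "epoch", ylab = "loss",
                 ylim = range(c(h$train_loss, h$val_loss)), ...)
  graphics::lines(h$epoch, h$val_loss, col = "firebrick")
  graphics::legend("topright", c("train", "validation"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Serializes a model to a single JSON file: the configuration, stage,
#' flattened weight vector, normalization running statistics, spline knot
#' grids and training history. `load_promkan()` rebuilds the architecture
#' from the stored configuration and restores all tensors exactly.
#'
#' @param model a `promkan` object.
#' @param path output / input file path.
#' @return `path` invisibly (save); the restored `promkan` object (load).
#' @export
save_promkan <- function(model, path) {
  grids <- lapply(model$params$blocks, function(b) b$kan$grid)
  obj <- list(
    format = "promkan-checkpoint-1",
    stage = model$stage,
    seed = model$seed,
    trained = model$trained,
    config = unclass(model$config),
    theta = unlist(model_trainable(model$params), use.names = FALSE),
    states = model_get_states(model$params),
    kan_grids = grids,
    history = model$history
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname save_promkan
#' @export
load_promkan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "promkan-checkpoint-1")) {
    stop("not a promkan checkpoint: ", path)
  }
  cfg <- do.call(promkan_config, obj$config[setdiff(names(obj$config), NULL)])
  model <- promkan_build(cfg, stage = obj$stage, seed = obj$seed)
  skel <- model_trainable(model$params)
  model$params <- model_set_trainable(model$params,
                                      utils::relist(obj$theta, skel))
  st <- obj$states
  model$params$ms$state$bn$mean <- as.numeric(st$ms_bn$bn$mean)
  model$params$ms$state$bn$var <- as.numeric(st$ms_bn$bn$var)
  for (i in seq_along(model$params$blocks)) {
    bs <- st$blocks[[i]]
    model$params$blocks[[i]]$state$main_bn$mean <- as.numeric(bs$main_bn$mean)
    model$params$blocks[[i]]$state$main_bn$var <- as.numeric(bs$main_bn$var)
    model$params$blocks[[i]]$state$short_bn$mean <- as.numeric(bs$short_bn$mean)
    model$params$blocks[[i]]$state$short_bn$var <- as.numeric(bs$short_bn$var)
    g <- if (is.array(obj$kan_grids) && length(dim(obj$kan_grids)) == 3L) {
      obj$kan_grids[i, , ]
    } else {
      obj$kan_grids[[i]]
    }
    model$params$blocks[[i]]$kan$grid <- matrix(as.numeric(g), nrow(g), ncol(g))
  }
  model$trained <- isTRUE(obj$trained)
  model$history <- if (!is.null(obj$history)) {
    as.data.frame(lapply(obj$history, unlist))
  } else NULL
  model
}
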