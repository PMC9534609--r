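#' Model configuration for the four-channel attention CNN-LSTM
#'
#' Each of the m selected clinical features is linearly embedded into a
#' length-`embed_dim` vector, and the m embeddings form a sequence. Four
#' parallel channels process the sequence; channel k concatenates a 1-D
#' convolution (kernel size `kernel_sizes[k]`, same padding, ReLU) with an
#' LSTM hidden-state sequence along the feature axis. Channel outputs are
#' max-pooled over time and concatenated into the hidden vector h; a
#' soft attention over the first channel's per-step `[hidden; cell]`
#' states produces a context vector that is concatenated with h before
#' the dense softmax head.
#'
#' @param embed_dim per-feature embedding size (16).
#' @param kernel_sizes convolution kernel size per channel (2, 3, 4, 5).
#' @param num_filters convolution filters per channel (32).
#' @param lstm_hidden LSTM hidden size per channel (32).
#' @param attention_dim size of the attention projection (32).
#' @param num_classes output classes (2).
#' @param dropout dropout rate applied to the merged hidden representation
#'   during training (0.2; inference is always deterministic).
#' @param seed seed for parameter initialization.
#' @return an `acnn_lstm_config` list.
#' @export
acnn_lstm_config <- function(embed_dim = 16, kernel_sizes = c(2, 3, 4, 5),
                             num_filters = 32, lstm_hidden = 32,
                             attention_dim = 32, num_classes = 2,
                             dropout = 0.2, seed = 1) {
  stopifnot(embed_dim >= 1, num_filters >= 1, lstm_hidden >= 1,
            attention_dim >= 1, num_classes >= 2, all(kernel_sizes >= 1),
            dropout >= 0, dropout < 1)
  structure(list(embed_dim = embed_dim, kernel_sizes = kernel_sizes,
                 num_filters = num_filters, lstm_hidden = lstm_hidden,
                 attention_dim = attention_dim, num_classes = num_classes,
                 dropout = dropout,
                 n_channels = length(kernel_sizes), seed = seed),
            class = "acnn_lstm_config")
}

#' Training configuration
#'
#' @param epochs maximum training epochs (200).
#' @param batch_size minibatch size (32).
#' @param learning_rate Adam step size (1e-3).
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping (20); `Inf` disables early stopping.
#' @param validation_fraction fraction of the training data held out for
#'   early stopping (0.15).
#' @param refit_full after early stopping has chosen the epoch count,
#'   retrain from scratch on the full training data (including the
#'   validation split) for that many epochs (TRUE). Ignored when early
#'   stopping is disabled.
#' @param seed seed for shuffling and the validation split.
#' @return an `acnn_train_config` list.
#' @export
acnn_train_config <- function(epochs = 200, batch_size = 32,
                              learning_rate = 1e-3,
                              early_stop_patience = 20,
                              validation_fraction = 0.15,
                              refit_full = TRUE, seed = 1) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            early_stop_patience > 0, validation_fraction >= 0,
            validation_fraction < 0.5)
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate,
                 early_stop_patience = early_stop_patience,
                 validation_fraction = validation_fraction,
                 refit_full = refit_full, seed = seed),
            class = "acnn_train_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

#' One LSTM cell step
#'
#' Gates over the concatenation `[h_prev, x_t]`:
#' `z = tanh(W_z . + b_z)`, `i, f, o = sigmoid(W . + b)`,
#' `c_t = f * c_prev + i * z`, `h_t = o * tanh(c_t)` (elementwise).
#'
#' @param w weight matrix of shape `(hidden + input) x (4 * hidden)`,
#'   columns grouped as z, i, f, o blocks.
#' @param b bias vector of length `4 * hidden`.
#' @param x_t input vector.
#' @param h_prev,c_prev previous hidden and cell state vectors.
#' @return list with `h` and `c`.
#' @export
lstm_cell <- function(w, b, x_t, h_prev, c_prev) {
  hh <- length(h_prev)
  if (nrow(w) != hh + length(x_t) || ncol(w) != 4 * hh ||
      length(b) != 4 * hh)
    stop("lstm_cell: parameter shapes inconsistent with inputs")
  a <- drop(c(h_prev, x_t) %*% w) + b
  z <- tanh(a[seq_len(hh)])
  i <- sigmoid(a[hh + seq_len(hh)])
  f <- sigmoid(a[2 * hh + seq_len(hh)])
  o <- sigmoid(a[3 * hh + seq_len(hh)])
  c_t <- f * c_prev + i * z
  list(h = o * tanh(c_t), c = c_t)
}

#' 1-D convolution over an embedded sequence
#'
#' @param x sequence matrix, `m x embed_dim` (one row per step).
#' @param kernel array `kernel_size x embed_dim x num_filters`.
#' @param bias length-`num_filters` vector.
#' @param padding `"same"` (output length m) or `"valid"` (length
#'   `m - kernel_size + 1`).
#' @param activation nonlinearity applied to the pre-activation map
#'   (ReLU by default; pass `identity` for the raw map).
#' @return matrix `out_len x num_filters`.
#' @export
conv_channel <- function(x, kernel, bias = NULL, padding = c("same", "valid"),
                         activation = function(v) pmax(v, 0)) {
  padding <- match.arg(padding)
  x <- as.matrix(x)
  ks <- dim(kernel)[1L]
  nf <- dim(kernel)[3L]
  if (dim(kernel)[2L] != ncol(x))
    stop("kernel depth does not match the embedding dimension")
  m <- nrow(x)
  if (padding == "valid" && ks > m)
    stop("kernel longer than the (unpadded) sequence")
  if (is.null(bias)) bias <- numeric(nf)
  pad_l <- if (padding == "same") (ks - 1L) %/% 2L else 0L
  out_len <- if (padding == "same") m else m - ks + 1L
  out <- matrix(rep(bias, each = out_len), out_len, nf)
  for (s in seq_len(ks)) {
    kmat <- matrix(kernel[s, , ], ncol(x), nf)
    for (t in seq_len(out_len)) {
      src <- t + s - 1L - pad_l
      if (src >= 1L && src <= m)
        out[t, ] <- out[t, ] + drop(x[src, ] %*% kmat)
    }
  }
  activation(out)
}

#' Attention over per-step LSTM states
#'
#' `h_i = [h'_t; c_t]` per step; scores `e_i = v_a' tanh(W_r h_i + b)`;
#' weights by softmax over steps; context `= sum_i w_i h_i`.
#'
#' @param h_seq matrix `T_x x hidden` of LSTM outputs.
#' @param c_seq matrix `T_x x hidden` of LSTM cell states.
#' @param w_r projection matrix `attention_dim x (2 * hidden)`.
#' @param b_r bias, length `attention_dim`.
#' @param v_a scoring vector, length `attention_dim`.
#' @return list with `context` (length `2 * hidden`) and `weights`
#'   (length `T_x`, on the simplex).
#' @export
attention <- function(h_seq, c_seq, w_r, b_r, v_a) {
  h_seq <- as.matrix(h_seq); c_seq <- as.matrix(c_seq)
  if (nrow(h_seq) == 0L) stop("attention requires at least one time step")
  hi <- cbind(h_seq, c_seq)
  u <- tanh(hi %*% t(w_r) + matrix(b_r, nrow(hi), length(b_r), byrow = TRUE))
  e <- drop(u %*% v_a)
  w <- drop(softmax_rows(matrix(e, 1L)))
  list(context = drop(w %*% hi), weights = w)
}

# ---- parameter initialization -------------------------------------------

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

init_params <- function(m, cfg) {
  e <- cfg$embed_dim; f <- cfg$num_filters; h <- cfg$lstm_hidden
  a <- cfg$attention_dim; nc <- cfg$n_channels
  p <- list(emb_w = glorot(m, e), emb_b = matrix(0, m, e))
  for (k in seq_len(nc)) {
    ks <- cfg$kernel_sizes[k]
    kw <- array(stats::runif(ks * e * f, -1, 1) * sqrt(6 / (ks * e + f)),
                c(ks, e, f))
    p[[paste0("conv_k", k)]] <- kw
    p[[paste0("conv_b", k)]] <- numeric(f)
    p[[paste0("lstm_w", k)]] <- glorot(h + e, 4 * h)
    p[[paste0("lstm_b", k)]] <- numeric(4 * h)
  }
  p$att_wr <- glorot(a, 2 * h)
  p$att_br <- numeric(a)
  p$att_va <- stats::runif(a, -0.1, 0.1)
  dz <- nc * (f + h) + 2 * h
  p$dense_w <- glorot(dz, cfg$num_classes)
  p$dense_b <- numeric(cfg$num_classes)
  p
}

# ---- batched forward pass ------------------------------------------------
# X: B x m matrix of raw (normalized) selected feature values.
# Returns probabilities and, when keep_cache, everything backward needs.

acnn_forward <- function(params, X, cfg, keep_cache = FALSE,
                         training = FALSE) {
  X <- as.matrix(X)
  bsz <- nrow(X); m <- ncol(X)
  e <- cfg$embed_dim; f <- cfg$num_filters; h <- cfg$lstm_hidden
  emb <- lapply(seq_len(m), function(j)
    outer(X[, j], params$emb_w[j, ]) +
      matrix(params$emb_b[j, ], bsz, e, byrow = TRUE))

  pooled <- vector("list", cfg$n_channels)
  ch_cache <- vector("list", cfg$n_channels)
  for (k in seq_len(cfg$n_channels)) {
    ks <- cfg$kernel_sizes[k]
    pad_l <- (ks - 1L) %/% 2L
    kw <- params[[paste0("conv_k", k)]]
    bc <- params[[paste0("conv_b", k)]]
    pre <- vector("list", m)
    for (t in seq_len(m)) {
      acc <- matrix(bc, bsz, f, byrow = TRUE)
      for (s in seq_len(ks)) {
        src <- t + s - 1L - pad_l
        if (src >= 1L && src <= m)
          acc <- acc + emb[[src]] %*% matrix(kw[s, , ], e, f)
      }
      pre[[t]] <- acc
    }
    conv_out <- lapply(pre, function(a) pmax(a, 0))

    w <- params[[paste0("lstm_w", k)]]
    b <- params[[paste0("lstm_b", k)]]
    h_seq <- c_seq <- gi <- gf <- go <- gz <- inp <- cprev <- vector("list", m)
    h_t <- c_t <- matrix(0, bsz, h)
    for (t in seq_len(m)) {
      inp[[t]] <- cbind(h_t, emb[[t]])
      cprev[[t]] <- c_t
      a <- inp[[t]] %*% w + matrix(b, bsz, 4 * h, byrow = TRUE)
      gz[[t]] <- tanh(a[, seq_len(h), drop = FALSE])
      gi[[t]] <- sigmoid(a[, h + seq_len(h), drop = FALSE])
      gf[[t]] <- sigmoid(a[, 2 * h + seq_len(h), drop = FALSE])
      go[[t]] <- sigmoid(a[, 3 * h + seq_len(h), drop = FALSE])
      c_t <- gf[[t]] * c_t + gi[[t]] * gz[[t]]
      h_t <- go[[t]] * tanh(c_t)
      h_seq[[t]] <- h_t
      c_seq[[t]] <- c_t
    }

    # channel output per step = conv (+ReLU) concat LSTM hidden; max-pool
    pool <- cbind(conv_out[[1L]], h_seq[[1L]])
    amax <- matrix(1L, bsz, f + h)
    if (m > 1L) for (t in 2L:m) {
      cand <- cbind(conv_out[[t]], h_seq[[t]])
      upd <- cand > pool
      pool[upd] <- cand[upd]
      amax[upd] <- t
    }
    pooled[[k]] <- pool
    ch_cache[[k]] <- list(pre = pre, conv_out = conv_out, h_seq = h_seq,
                          c_seq = c_seq, gi = gi, gf = gf, go = go,
                          gz = gz, inp = inp, cprev = cprev, amax = amax)
  }

  # attention over channel 1's [hidden; cell] sequences
  hs1 <- ch_cache[[1L]]$h_seq; cs1 <- ch_cache[[1L]]$c_seq
  a_dim <- cfg$attention_dim
  u <- vector("list", m)
  escore <- matrix(0, bsz, m)
  for (t in seq_len(m)) {
    hi <- cbind(hs1[[t]], cs1[[t]])
    u[[t]] <- tanh(hi %*% t(params$att_wr) +
                     matrix(params$att_br, bsz, a_dim, byrow = TRUE))
    escore[, t] <- u[[t]] %*% params$att_va
  }
  aw <- softmax_rows(escore)
  context <- matrix(0, bsz, 2 * h)
  for (t in seq_len(m))
    context <- context + aw[, t] * cbind(hs1[[t]], cs1[[t]])

  z_full <- cbind(do.call(cbind, pooled), context)
  drop_mask <- NULL
  z_in <- z_full
  if (training && cfg$dropout > 0) {
    # inverted dropout: inference needs no rescaling
    drop_mask <- matrix(stats::runif(length(z_full)) >= cfg$dropout,
                        bsz, ncol(z_full)) / (1 - cfg$dropout)
    z_in <- z_full * drop_mask
  }
  logits <- z_in %*% params$dense_w +
    matrix(params$dense_b, bsz, cfg$num_classes, byrow = TRUE)
  probs <- softmax_rows(logits)
  out <- list(probs = probs)
  if (keep_cache)
    out$cache <- list(X = X, emb = emb, ch = ch_cache, u = u, aw = aw,
                      context = context, z_full = z_full, z_in = z_in,
                      drop_mask = drop_mask, m = m, bsz = bsz)
  out
}

# ---- batched backward pass ----------------------------------------------
# dlogits: B x num_classes gradient of the loss w.r.t. the logits.

acnn_backward <- function(params, cfg, cache, dlogits) {
  m <- cache$m; bsz <- cache$bsz
  e <- cfg$embed_dim; f <- cfg$num_filters; h <- cfg$lstm_hidden
  g <- list()
  g$dense_w <- t(cache$z_in) %*% dlogits
  g$dense_b <- colSums(dlogits)
  dz_full <- dlogits %*% t(params$dense_w)
  if (!is.null(cache$drop_mask)) dz_full <- dz_full * cache$drop_mask

  d_emb <- lapply(seq_len(m), function(t) matrix(0, bsz, e))
  fh <- f + h
  dcontext <- dz_full[, cfg$n_channels * fh + seq_len(2 * h), drop = FALSE]

  # attention backward (feeds channel 1's state gradients)
  hs1 <- cache$ch[[1L]]$h_seq; cs1 <- cache$ch[[1L]]$c_seq
  aw <- cache$aw
  dw_att <- matrix(0, bsz, m)
  for (t in seq_len(m))
    dw_att[, t] <- rowSums(dcontext * cbind(hs1[[t]], cs1[[t]]))
  de <- aw * (dw_att - rowSums(aw * dw_att))
  g$att_wr <- matrix(0, cfg$attention_dim, 2 * h)
  g$att_br <- numeric(cfg$attention_dim)
  g$att_va <- numeric(cfg$attention_dim)
  dh1_ext <- dc1_ext <- lapply(seq_len(m), function(t) matrix(0, bsz, h))
  for (t in seq_len(m)) {
    hi <- cbind(hs1[[t]], cs1[[t]])
    du <- outer(de[, t], params$att_va)
    da <- du * (1 - cache$u[[t]]^2)
    g$att_wr <- g$att_wr + t(da) %*% hi
    g$att_br <- g$att_br + colSums(da)
    g$att_va <- g$att_va + colSums(de[, t] * cache$u[[t]])
    dhi <- aw[, t] * dcontext + da %*% params$att_wr
    dh1_ext[[t]] <- dhi[, seq_len(h), drop = FALSE]
    dc1_ext[[t]] <- dhi[, h + seq_len(h), drop = FALSE]
  }

  for (k in seq_len(cfg$n_channels)) {
    cc <- cache$ch[[k]]
    dP <- dz_full[, (k - 1L) * fh + seq_len(fh), drop = FALSE]
    # un-pool: route gradient to the argmax timestep
    dconv <- lapply(seq_len(m), function(t) matrix(0, bsz, f))
    dh_ext <- lapply(seq_len(m), function(t) matrix(0, bsz, h))
    for (t in seq_len(m)) {
      sel <- cc$amax == t
      dCH <- matrix(0, bsz, fh)
      dCH[sel] <- dP[sel]
      dconv[[t]] <- dCH[, seq_len(f), drop = FALSE]
      dh_ext[[t]] <- dCH[, f + seq_len(h), drop = FALSE]
    }
    if (k == 1L)
      for (t in seq_len(m)) dh_ext[[t]] <- dh_ext[[t]] + dh1_ext[[t]]

    # conv backward
    ks <- cfg$kernel_sizes[k]
    pad_l <- (ks - 1L) %/% 2L
    kw <- params[[paste0("conv_k", k)]]
    gk <- array(0, dim(kw))
    gb <- numeric(f)
    for (t in seq_len(m)) {
      dpre <- dconv[[t]] * (cc$pre[[t]] > 0)
      gb <- gb + colSums(dpre)
      for (s in seq_len(ks)) {
        src <- t + s - 1L - pad_l
        if (src >= 1L && src <= m) {
          gk[s, , ] <- gk[s, , ] + t(cache$emb[[src]]) %*% dpre
          d_emb[[src]] <- d_emb[[src]] + dpre %*% t(matrix(kw[s, , ], e, f))
        }
      }
    }
    g[[paste0("conv_k", k)]] <- gk
    g[[paste0("conv_b", k)]] <- gb

    # LSTM backward through time
    w <- params[[paste0("lstm_w", k)]]
    gw <- matrix(0, nrow(w), ncol(w))
    gbl <- numeric(4 * h)
    dh_next <- dc_next <- matrix(0, bsz, h)
    for (t in rev(seq_len(m))) {
      dh <- dh_ext[[t]] + dh_next
      tc <- tanh(cc$c_seq[[t]])
      dc <- dc_next + dh * cc$go[[t]] * (1 - tc^2)
      if (k == 1L) dc <- dc + dc1_ext[[t]]
      do_ <- dh * tc
      df <- dc * cc$cprev[[t]]
      di <- dc * cc$gz[[t]]
      dzg <- dc * cc$gi[[t]]
      da <- cbind(dzg * (1 - cc$gz[[t]]^2),
                  di * cc$gi[[t]] * (1 - cc$gi[[t]]),
                  df * cc$gf[[t]] * (1 - cc$gf[[t]]),
                  do_ * cc$go[[t]] * (1 - cc$go[[t]]))
      gw <- gw + t(cc$inp[[t]]) %*% da
      gbl <- gbl + colSums(da)
      dinp <- da %*% t(w)
      dh_next <- dinp[, seq_len(h), drop = FALSE]
      d_emb[[t]] <- d_emb[[t]] + dinp[, h + seq_len(e), drop = FALSE]
      dc_next <- dc * cc$gf[[t]]
    }
    g[[paste0("lstm_w", k)]] <- gw
    g[[paste0("lstm_b", k)]] <- gbl
  }

  g$emb_w <- matrix(0, m, e)
  g$emb_b <- matrix(0, m, e)
  for (j in seq_len(m)) {
    g$emb_w[j, ] <- colSums(cache$X[, j] * d_emb[[j]])
    g$emb_b[j, ] <- colSums(d_emb[[j]])
  }
  g
}

# mean cross-entropy and the logit gradient for one-hot labels y (0/1)
ce_loss_grad <- function(probs, y) {
  bsz <- nrow(probs)
  idx <- cbind(seq_len(bsz), y + 1L)
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / bsz)
}

# loss (and optionally gradients) over a full batch
acnn_loss <- function(params, X, y, cfg, with_grad = FALSE,
                      training = with_grad) {
  fw <- acnn_forward(params, X, cfg, keep_cache = with_grad,
                     training = training)
  lg <- ce_loss_grad(fw$probs, y)
  if (!with_grad) return(list(loss = lg$loss))
  list(loss = lg$loss,
       grads = acnn_backward(params, cfg, fw$cache, lg$dlogits))
}

#' Train the attention CNN-LSTM
#'
#' Minimizes the cross-entropy with Adam on minibatches; a fraction of the
#' training rows is held out for early stopping, and the parameters with
#' the best validation loss are restored.
#'
#' @param table a preprocessed [clinical_table()].
#' @param subset optional [feature_subset()] restricting the input
#'   features (default: all).
#' @param model_cfg an [acnn_lstm_config()].
#' @param train_cfg an [acnn_train_config()].
#' @return an `acnn_lstm` model with elements `params`, `model_cfg`,
#'   `subset`, `history` (per-epoch train/validation loss).
#' @export
acnn_lstm_train <- function(table, subset = NULL,
                            model_cfg = acnn_lstm_config(),
                            train_cfg = acnn_train_config()) {
  stopifnot(inherits(table, "clinical_table"))
  if (any(table$missing_mask)) stop("impute missing values before training")
  if (is.null(subset)) subset <- feature_subset(rep(TRUE, table$d))
  X <- table$values[, subset$mask, drop = FALSE]
  y <- table$labels
  m <- ncol(X)
  set.seed(train_cfg$seed)
  n <- nrow(X)
  n_val <- floor(train_cfg$validation_fraction * n)
  use_val <- n_val >= 2 && is.finite(train_cfg$early_stop_patience)
  val_idx <- if (use_val) sample(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)

  run <- train_loop(X, y, tr_idx, val_idx, model_cfg, train_cfg,
                    max_epochs = train_cfg$epochs,
                    patience = if (use_val) train_cfg$early_stop_patience
                               else Inf)
  params <- run$params
  history <- run$history
  if (use_val && isTRUE(train_cfg$refit_full)) {
    set.seed(train_cfg$seed)
    refit <- train_loop(X, y, seq_len(n), integer(0), model_cfg, train_cfg,
                        max_epochs = run$best_epoch, patience = Inf)
    params <- refit$params
  }
  structure(list(params = params, model_cfg = model_cfg,
                 subset = subset, history = history),
            class = "acnn_lstm")
}

# minibatch Adam loop with optional validation-based early stopping;
# returns the best (lowest-monitor) parameters and the epoch they came from
train_loop <- function(X, y, tr_idx, val_idx, model_cfg, train_cfg,
                       max_epochs, patience) {
  params <- local({ set.seed(model_cfg$seed); init_params(ncol(X), model_cfg) })
  opt <- adam_state(params)
  best <- list(loss = Inf, params = params, epoch = 1L)
  wait <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  for (ep in seq_len(max_epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = train_cfg$batch_size)) {
      bi <- ord[start:min(start + train_cfg$batch_size - 1L, length(ord))]
      lg <- acnn_loss(params, X[bi, , drop = FALSE], y[bi], model_cfg,
                      with_grad = TRUE)
      if (!is.finite(lg$loss))
        stop(sprintf("non-finite training loss at epoch %d", ep))
      upd <- adam_update(params, lg$grads, opt, train_cfg$learning_rate)
      params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    vl <- if (length(val_idx))
      acnn_loss(params, X[val_idx, , drop = FALSE], y[val_idx],
                model_cfg)$loss else NA_real_
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = ep_loss / nb,
                                         val_loss = vl))
    monitor <- if (length(val_idx)) vl else ep_loss / nb
    if (monitor < best$loss - 1e-6) {
      best <- list(loss = monitor, params = params, epoch = ep)
      wait <- 0L
    } else if (is.finite(patience)) {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  final <- if (is.finite(patience)) best$params else params
  list(params = final, history = history, best_epoch = best$epoch)
}

#' @export
print.acnn_lstm <- function(x, ...) {
  npar <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "acnn_lstm: %d input features, %d channels (kernels %s), %d parameters\n",
    x$subset$size, x$model_cfg$n_channels,
    paste(x$model_cfg$kernel_sizes, collapse = "/"), npar))
  cat(sprintf("  trained %d epochs\n", nrow(x$history)))
  invisible(x)
}

#' Class probabilities for new data
#'
#' @param object a trained `acnn_lstm` model.
#' @param newdata a [clinical_table()] (the model's feature subset is
#'   applied) or a numeric matrix already restricted to the subset.
#' @param ... unused.
#' @return matrix of class probabilities, one row per sample, columns
#'   `absence` and `presence`.
#' @export
predict.acnn_lstm <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "clinical_table"))
    newdata$values[, object$subset$mask, drop = FALSE]
  else as.matrix(newdata)
  p <- acnn_forward(object$params, X, object$model_cfg)$probs
  colnames(p) <- c("absence", "presence")
  p
}

#' Classify one feature vector
#'
#' @param x numeric vector of the model's selected features.
#' @param model a trained `acnn_lstm`.
#' @return named probability vector summing to 1.
#' @export
classify <- function(x, model) {
  drop(predict(model, matrix(x, nrow = 1L)))
}

#' Fold classifier adapter for [run_iterations()]
#'
#' @param model_cfg an [acnn_lstm_config()].
#' @param train_cfg an [acnn_train_config()].
#' @return a `(train_table, test_table) -> labels` function.
#' @export
acnn_lstm_fold_classifier <- function(model_cfg = acnn_lstm_config(),
                                      train_cfg = acnn_train_config()) {
  function(train_table, test_table) {
    fit <- acnn_lstm_train(train_table, model_cfg = model_cfg,
                           train_cfg = train_cfg)
    as.integer(predict(fit, test_table)[, "presence"] > 0.5)
  }
}

# ---- Adam ----------------------------------------------------------------

adam_state <- function(params) {
  zero <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(m = zero, v = zero, t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_update <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gnm
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gnm^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) /
        (sqrt(state$v[[nm]] / corr2) + state$eps)
  }
  list(params = params, state = state)
}
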