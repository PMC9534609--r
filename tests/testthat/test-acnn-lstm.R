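test_that("the LSTM cell matches hand-evaluated zero-parameter cases", {
  h <- 3
  w <- matrix(0, h + 2, 4 * h)
  b <- numeric(4 * h)
  # all parameters zero, zero cell state: gates 0.5, z = 0 -> h = c = 0
  out <- lstm_cell(w, b, x_t = c(1, -1), h_prev = numeric(h),
                   c_prev = numeric(h))
  expect_equal(out$h, numeric(h))
  expect_equal(out$c, numeric(h))
  # zero parameters, c_prev = 1: c = f * 1 = 0.5, h = 0.5 * tanh(0.5)
  out1 <- lstm_cell(w, b, x_t = c(1, -1), h_prev = numeric(h),
                    c_prev = rep(1, h))
  expect_equal(out1$c, rep(0.5, h))
  expect_equal(out1$h, rep(0.5 * tanh(0.5), h), tolerance = 1e-12)
  expect_equal(out1$h[1], 0.23106, tolerance = 1e-4)
  expect_error(lstm_cell(w, b, x_t = c(1, -1, 0), h_prev = numeric(h),
                         c_prev = numeric(h)), "shapes")
})

test_that("LSTM gates stay in (0,1) and |h| < 1 on random inputs", {
  set.seed(4)
  h <- 4
  w <- matrix(rnorm((h + 3) * 4 * h), h + 3, 4 * h)
  b <- rnorm(4 * h)
  for (i in 1:10) {
    out <- lstm_cell(w, b, rnorm(3), rnorm(h, sd = 0.5), rnorm(h))
    expect_true(all(abs(out$h) < 1))
  }
})

test_that("the 1-D convolution reduces to a moving sum for a ones kernel", {
  x <- matrix(1, 4, 1)  # sequence (1,1,1,1), embedding dim 1
  kernel <- array(1, c(2, 1, 1))
  out <- conv_channel(x, kernel, padding = "valid", activation = identity)
  expect_equal(drop(out), c(2, 2, 2))
  # zero kernel with bias b gives the constant map b
  outb <- conv_channel(x, array(0, c(2, 1, 1)), bias = 3,
                       padding = "valid", activation = identity)
  expect_equal(drop(outb), rep(3, 3))
  # same padding preserves the sequence length for any kernel size
  set.seed(1)
  xs <- matrix(rnorm(12), 4, 3)
  for (ks in 1:5) {
    o <- conv_channel(xs, array(rnorm(ks * 3 * 2), c(ks, 3, 2)))
    expect_equal(dim(o), c(4L, 2L))
  }
  expect_error(conv_channel(xs, array(1, c(5, 3, 2)), padding = "valid"),
               "longer")
})

test_that("attention weights lie on the simplex and recover known cases", {
  set.seed(7)
  h <- 3; a <- 2; tx <- 5
  w_r <- matrix(rnorm(a * 2 * h), a, 2 * h)
  b_r <- rnorm(a); v_a <- rnorm(a)
  h_seq <- matrix(rnorm(tx * h), tx, h)
  c_seq <- matrix(rnorm(tx * h), tx, h)
  att <- attention(h_seq, c_seq, w_r, b_r, v_a)
  expect_equal(sum(att$weights), 1, tolerance = 1e-12)
  expect_true(all(att$weights > 0))
  # identical steps give uniform weights and the mean state
  h1 <- matrix(rep(h_seq[1, ], tx), tx, byrow = TRUE)
  c1 <- matrix(rep(c_seq[1, ], tx), tx, byrow = TRUE)
  att_u <- attention(h1, c1, w_r, b_r, v_a)
  expect_equal(att_u$weights, rep(1 / tx, tx), tolerance = 1e-12)
  expect_equal(att_u$context, c(h_seq[1, ], c_seq[1, ]), tolerance = 1e-12)
  # a single step takes all the weight
  att_1 <- attention(h_seq[1, , drop = FALSE], c_seq[1, , drop = FALSE],
                     w_r, b_r, v_a)
  expect_equal(att_1$weights, 1)
  expect_equal(att_1$context, c(h_seq[1, ], c_seq[1, ]))
  expect_error(attention(h_seq[0, , drop = FALSE], c_seq[0, , drop = FALSE],
                         w_r, b_r, v_a), "time step")
})

test_that("the forward pass yields valid probabilities for any input width", {
  cfg <- tiny_model_cfg()
  for (m in c(1L, 2L, 5L, 13L)) {
    set.seed(m)
    params <- cardiofs:::init_params(m, cfg)
    X <- matrix(runif(3 * m), 3, m)
    p <- cardiofs:::acnn_forward(params, X, cfg)$probs
    expect_equal(dim(p), c(3L, 2L))
    expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
    expect_true(all(p > 0))
  }
})

test_that("inference is deterministic and zero logits give (0.5, 0.5)", {
  cfg <- tiny_model_cfg()
  set.seed(2)
  params <- cardiofs:::init_params(4, cfg)
  X <- matrix(runif(8), 2, 4)
  p1 <- cardiofs:::acnn_forward(params, X, cfg)$probs
  p2 <- cardiofs:::acnn_forward(params, X, cfg)$probs
  expect_identical(p1, p2)
  params$dense_w[] <- 0
  params$dense_b[] <- 0
  p0 <- cardiofs:::acnn_forward(params, X, cfg)$probs
  expect_equal(p0, matrix(0.5, 2, 2), ignore_attr = TRUE)
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- tiny_model_cfg()
  set.seed(3)
  m <- 4
  params <- cardiofs:::init_params(m, cfg)
  X <- matrix(runif(3 * m), 3, m)
  y <- c(0L, 1L, 1L)
  lg <- cardiofs:::acnn_loss(params, X, y, cfg, with_grad = TRUE)
  eps <- 1e-4
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (cardiofs:::acnn_loss(pp, X, y, cfg)$loss -
               cardiofs:::acnn_loss(pm, X, y, cfg)$loss) / (2 * eps)
      an <- lg$grads[[nm]][i]
      expect_lt(abs(fd - an), 1e-4 * max(1, abs(fd) + abs(an)))
    }
  }
})

test_that("channel output width is filters + hidden and merging concatenates", {
  cfg <- tiny_model_cfg()
  set.seed(5)
  m <- 5
  params <- cardiofs:::init_params(m, cfg)
  X <- matrix(runif(2 * m), 2, m)
  fw <- cardiofs:::acnn_forward(params, X, cfg, keep_cache = TRUE)
  fh <- cfg$num_filters + cfg$lstm_hidden
  expect_equal(ncol(fw$cache$z_full),
               cfg$n_channels * fh + 2 * cfg$lstm_hidden)
  # pooled block k is the elementwise max over steps of channel k's output
  cc <- fw$cache$ch[[1]]
  stacked <- sapply(seq_len(m), function(t)
    cbind(cc$conv_out[[t]], cc$h_seq[[t]])[1, ])
  expect_equal(fw$cache$z_full[1, seq_len(fh)], apply(stacked, 1L, max))
})

test_that("training memorizes a small random sample and is seeded", {
  set.seed(31)
  n <- 50
  tab <- clinical_table(matrix(runif(n * 4), n, 4),
                        labels = rep_len(c(0L, 1L), n))
  cfg <- acnn_lstm_config(dropout = 0, seed = 7)
  tcfg <- acnn_train_config(epochs = 300, batch_size = 16,
                            learning_rate = 3e-3,
                            validation_fraction = 0, seed = 7)
  fit <- acnn_lstm_train(tab, model_cfg = cfg, train_cfg = tcfg)
  acc <- mean((predict(fit, tab)[, "presence"] > 0.5) == (tab$labels == 1))
  expect_gte(acc, 0.95)  # capacity: near-zero training error
})

test_that("training loss trends downward on separable data without early stopping", {
  tab <- normalize_table(separable_table(n = 60, d = 2, k = 2, effect = 3,
                                         seed = 8))
  cfg <- acnn_lstm_config(embed_dim = 4, kernel_sizes = c(2, 2),
                          num_filters = 4, lstm_hidden = 4,
                          attention_dim = 4, dropout = 0, seed = 2)
  fit <- acnn_lstm_train(tab, model_cfg = cfg,
                         train_cfg = acnn_train_config(
                           epochs = 40, learning_rate = 5e-4,
                           validation_fraction = 0, seed = 2))
  l <- fit$history$train_loss
  # smoothed trend: final quarter well below the first quarter
  expect_lt(mean(tail(l, 10)), mean(head(l, 10)))
  expect_lt(tail(l, 1), l[1])
  # same seeds and config reproduce the final parameters exactly
  refit <- acnn_lstm_train(tab, model_cfg = cfg,
                           train_cfg = acnn_train_config(
                             epochs = 40, learning_rate = 5e-4,
                             validation_fraction = 0, seed = 2))
  expect_identical(fit$params, refit$params)
})
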