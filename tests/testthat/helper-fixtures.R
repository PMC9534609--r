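# Small in-code fixtures shared across the test files.

# a tiny deterministic clinical table
toy_table <- function(n = 20, d = 4, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(n * d), n, d)
  labels <- rep_len(c(0L, 1L), n)
  clinical_table(vals, labels)
}

# a separable table: features 1..k shifted by `effect` for the positive class
separable_table <- function(n = 60, d = 4, k = 2, effect = 3, seed = 1) {
  set.seed(seed)
  labels <- rep_len(c(0L, 1L), n)
  vals <- matrix(rnorm(n * d), n, d)
  vals[, seq_len(k)] <- vals[, seq_len(k)] + labels * effect
  clinical_table(vals, labels)
}

# a small model configuration that keeps network tests fast
tiny_model_cfg <- function(seed = 3) {
  acnn_lstm_config(embed_dim = 3, kernel_sizes = c(2, 3), num_filters = 2,
                   lstm_hidden = 2, attention_dim = 2, dropout = 0,
                   seed = seed)
}

# write a Cleveland-dialect CSV from a character matrix of cells
write_cleveland_lines <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# independent externally-studentized residuals oracle: leave-one-out
# formula from the hat matrix of the regression of y on X
oracle_rstudent <- function(y, X) {
  Xd <- cbind(1, X)
  qrX <- qr(Xd)
  h <- rowSums(qr.Q(qrX)^2)
  e <- y - Xd %*% qr.coef(qrX, y)
  n <- length(y); p <- ncol(Xd)
  s2 <- sum(e^2) / (n - p)
  s2_i <- (s2 * (n - p) - e^2 / (1 - h)) / (n - p - 1)
  drop(e / sqrt(s2_i * (1 - h)))
}
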