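#' Synthetic clinical data configuration
#'
#' The generator emulates the shape of the Cleveland heart-disease table:
#' 303 samples, 13 numeric features of which a minority carry class
#' signal, a binary presence/absence label with the Cleveland positive
#' fraction, and a small rate of missing cells.
#'
#' @param n number of samples (303).
#' @param d number of features (13).
#' @param k_informative number of signal-carrying features (4).
#' @param effect_size class mean shift on informative features, in units
#'   of the noise standard deviation (1.5).
#' @param class_balance positive-class fraction (139/303).
#' @param missing_rate fraction of cells masked as missing (0.02).
#' @param noise_sd feature standard deviation (1).
#' @param categorical if TRUE a third of the features are discretized into
#'   small integer codes, mimicking Cleveland's categorical columns.
#' @param seed integer seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n = 303, d = 13, k_informative = 4,
                         effect_size = 1.5, class_balance = 139 / 303,
                         missing_rate = 0.02, noise_sd = 1,
                         categorical = FALSE, seed = 1) {
  stopifnot(k_informative >= 1, k_informative <= d,
            missing_rate >= 0, missing_rate < 1,
            class_balance > 0, class_balance < 1, noise_sd > 0)
  structure(list(n = n, d = d, k_informative = k_informative,
                 effect_size = effect_size, class_balance = class_balance,
                 missing_rate = missing_rate, noise_sd = noise_sd,
                 categorical = categorical, seed = seed),
            class = "synth_config")
}

#' Generate a synthetic Cleveland-like clinical table
#'
#' Labels are Bernoulli(`class_balance`); informative features are drawn
#' from Normal(label * effect_size, noise_sd), noise features from
#' Normal(0, noise_sd); missing cells are masked uniformly at random.
#'
#' @param cfg a [synth_config()].
#' @return a [clinical_table()] with attribute `"informative"` holding the
#'   planted 1-based informative feature indices.
#' @export
generate_clinical <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  labels <- stats::rbinom(cfg$n, 1L, cfg$class_balance)
  # guard against a degenerate single-class draw at tiny n
  if (length(unique(labels)) < 2L) labels[1:2] <- c(0L, 1L)
  informative <- sort(sample(cfg$d, cfg$k_informative))
  vals <- matrix(stats::rnorm(cfg$n * cfg$d, sd = cfg$noise_sd),
                 cfg$n, cfg$d)
  vals[, informative] <- vals[, informative] +
    labels * cfg$effect_size
  if (cfg$categorical) {
    cat_idx <- setdiff(seq_len(cfg$d), informative)
    cat_idx <- cat_idx[seq_len(min(length(cat_idx), ceiling(cfg$d / 3)))]
    for (j in cat_idx)
      vals[, j] <- as.numeric(cut(vals[, j], breaks = c(-Inf, -0.5, 0.5, Inf),
                                  labels = FALSE)) - 1
  }
  mask <- matrix(stats::runif(cfg$n * cfg$d) < cfg$missing_rate,
                 cfg$n, cfg$d)
  # never blank out an entire feature
  for (j in which(colSums(!mask) == 0L)) mask[1L, j] <- FALSE
  vals[mask] <- NA_real_
  res <- clinical_table(vals, labels, missing_mask = mask)
  attr(res, "informative") <- informative
  res
}

#' Standard benchmark objectives
#'
#' Closed-form test functions with global minimum 0: sphere (at the
#' origin), Rastrigin (at the origin), Rosenbrock (at the all-ones point).
#'
#' @param name one of `"sphere"`, `"rastrigin"`, `"rosenbrock"`.
#' @return a function mapping a numeric vector to a scalar cost.
#' @export
benchmark_objective <- function(name = c("sphere", "rastrigin",
                                         "rosenbrock")) {
  switch(match.arg(name),
    sphere = function(x) sum(x^2),
    rastrigin = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
    rosenbrock = function(x) {
      if (length(x) < 2) return((1 - x)^2)
      i <- seq_len(length(x) - 1L)
      sum(100 * (x[i + 1L] - x[i]^2)^2 + (1 - x[i])^2)
    })
}
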