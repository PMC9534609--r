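#' Preprocessing configuration
#'
#' @param missing_strategy imputation statistic for missing cells,
#'   `"median"` (default) or `"mean"`.
#' @param studentized_threshold absolute externally-studentized-residual
#'   cutoff above which a cell is treated as noise and repaired (default 3).
#' @param normalization `"minmax"` (default, maps each feature to \[0, 1\])
#'   or `"zscore"`.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(missing_strategy = c("median", "mean"),
                              studentized_threshold = 3,
                              normalization = c("minmax", "zscore")) {
  missing_strategy <- match.arg(missing_strategy)
  normalization <- match.arg(normalization)
  if (!is.numeric(studentized_threshold) || studentized_threshold <= 0)
    stop("`studentized_threshold` must be a positive number")
  structure(list(missing_strategy = missing_strategy,
                 studentized_threshold = studentized_threshold,
                 normalization = normalization),
            class = "preprocess_config")
}

#' Impute missing cells
#'
#' Replaces each masked cell with the per-feature median (or mean) of the
#' observed cells of that feature. Observed cells are untouched.
#'
#' @param table a [clinical_table()].
#' @param cfg a [preprocess_config()].
#' @return the table with `missing_mask` all-FALSE.
#' @export
impute_missing <- function(table, cfg = preprocess_config()) {
  stopifnot(inherits(table, "clinical_table"))
  if (!any(table$missing_mask)) return(table)
  stat <- switch(cfg$missing_strategy, median = stats::median, mean = mean)
  vals <- table$values
  for (j in seq_len(table$d)) {
    m <- table$missing_mask[, j]
    if (!any(m)) next
    if (all(m))
      stop(sprintf("feature '%s' is entirely missing; no statistic defined",
                   table$feature_names[j]))
    vals[m, j] <- stat(vals[!m, j])
  }
  clinical_table(vals, table$labels,
                 missing_mask = matrix(FALSE, table$n, table$d),
                 feature_names = table$feature_names)
}

#' Repair noisy cells by median studentized residuals
#'
#' For each feature j, fits the least-squares regression of feature j on
#' all remaining features and computes externally studentized residuals.
#' Cells whose absolute studentized residual exceeds the threshold are
#' replaced by the feature's median. When the design matrix is singular the
#' residual falls back to the robust (value - median) / MAD studentization,
#' with a notice.
#'
#' @param table a [clinical_table()] with no missing values.
#' @param cfg a [preprocess_config()].
#' @return the repaired table, with attribute `"n_replaced"` giving the
#'   number of repaired cells.
#' @export
remove_noise_studentized <- function(table, cfg = preprocess_config()) {
  stopifnot(inherits(table, "clinical_table"))
  if (any(table$missing_mask))
    stop("impute missing values before studentized noise removal")
  vals <- table$values
  thr <- cfg$studentized_threshold
  n_replaced <- 0L
  for (j in seq_len(table$d)) {
    y <- vals[, j]
    X <- vals[, -j, drop = FALSE]
    r <- tryCatch({
      fit <- stats::lm(y ~ X)
      if (any(is.na(stats::coef(fit)))) stop("singular design")
      stats::rstudent(fit)
    }, error = function(e) {
      message(sprintf(
        "feature '%s': singular design, falling back to (x - median)/MAD",
        table$feature_names[j]))
      md <- stats::mad(y)
      if (md == 0) rep(0, length(y)) else (y - stats::median(y)) / md
    })
    out <- which(is.finite(r) & abs(r) > thr)
    if (length(out)) {
      vals[out, j] <- stats::median(y)
      n_replaced <- n_replaced + length(out)
    }
  }
  res <- clinical_table(vals, table$labels,
                        missing_mask = table$missing_mask,
                        feature_names = table$feature_names)
  attr(res, "n_replaced") <- n_replaced
  res
}

#' Normalize features
#'
#' Min-max maps each feature affinely onto \[0, 1\] (constant features map
#' to 0); z-score centres and scales. The fitted per-feature parameters are
#' attached as attribute `"norm_params"` so they can be applied to held-out
#' data with [apply_normalization()].
#'
#' @param table a [clinical_table()] with no missing values.
#' @param cfg a [preprocess_config()].
#' @return the normalized table.
#' @export
normalize_table <- function(table, cfg = preprocess_config()) {
  stopifnot(inherits(table, "clinical_table"))
  if (any(table$missing_mask))
    stop("impute missing values before normalization")
  params <- fit_normalization(table$values, cfg$normalization)
  vals <- apply_norm_matrix(table$values, params)
  res <- clinical_table(vals, table$labels,
                        missing_mask = table$missing_mask,
                        feature_names = table$feature_names)
  attr(res, "norm_params") <- params
  res
}

fit_normalization <- function(values, method) {
  if (method == "minmax") {
    lo <- apply(values, 2L, min)
    hi <- apply(values, 2L, max)
    list(method = "minmax", lo = lo, hi = hi)
  } else {
    mu <- colMeans(values)
    sd <- apply(values, 2L, stats::sd)
    list(method = "zscore", mu = mu, sd = sd)
  }
}

apply_norm_matrix <- function(values, params) {
  if (params$method == "minmax") {
    rng <- params$hi - params$lo
    rng[rng == 0] <- 1  # constant features map to 0
    sweep(sweep(values, 2L, params$lo, "-"), 2L, rng, "/")
  } else {
    sd <- params$sd
    sd[sd == 0] <- 1
    sweep(sweep(values, 2L, params$mu, "-"), 2L, sd, "/")
  }
}

#' Apply previously fitted normalization parameters
#'
#' Used to transform held-out data with parameters fitted on training data
#' only (avoids information leakage in cross-validation).
#'
#' @param table a [clinical_table()].
#' @param params the `"norm_params"` attribute of a table returned by
#'   [normalize_table()].
#' @return the transformed table.
#' @export
apply_normalization <- function(table, params) {
  stopifnot(inherits(table, "clinical_table"))
  vals <- apply_norm_matrix(table$values, params)
  if (params$method == "minmax") vals <- pmin(pmax(vals, 0), 1)
  clinical_table(vals, table$labels, missing_mask = table$missing_mask,
                 feature_names = table$feature_names)
}

#' Full preprocessing pipeline
#'
#' Imputation, studentized-residual noise repair, then normalization.
#'
#' @inheritParams impute_missing
#' @return the preprocessed table: mask all-FALSE, every value in \[0, 1\]
#'   under the default min-max normalization.
#' @export
preprocess <- function(table, cfg = preprocess_config()) {
  table <- impute_missing(table, cfg)
  table <- remove_noise_studentized(table, cfg)
  normalize_table(table, cfg)
}
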