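#' Feature-selection fitness configuration
#'
#' The wrapper fitness of a candidate subset Y out of T features is the
#' convex combination `alpha * error + (1 - alpha) * |Y| / |T|`, where the
#' error is the stratified cross-validated misclassification rate of the
#' wrapper classifier on the masked feature matrix. Both terms lie in
#' \[0, 1\], so the fitness does too.
#'
#' @param alpha weight of the classification error (default 0.99; the
#'   subset-size term then acts as a tie-breaker).
#' @param wrapper classifier used to estimate the error; `"knn"` (k
#'   nearest neighbours) is the fast default.
#' @param knn_k neighbourhood size for the k-NN wrapper (odd values avoid
#'   voting ties on binary labels).
#' @param cv_folds number of stratified cross-validation folds.
#' @param seed integer seed fixing the fold assignment, so the fitness is
#'   a deterministic function of the mask.
#' @return a `fitness_config` list.
#' @export
fitness_config <- function(alpha = 0.99, wrapper = c("knn"), knn_k = 5,
                           cv_folds = 10, seed = 1) {
  wrapper <- match.arg(wrapper)
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]")
  if (cv_folds < 2) stop("`cv_folds` must be at least 2")
  structure(list(alpha = alpha, beta = 1 - alpha, wrapper = wrapper,
                 knn_k = knn_k, cv_folds = cv_folds, seed = seed),
            class = "fitness_config")
}

#' Map a continuous position to a feature subset
#'
#' Feature j is selected iff its coordinate exceeds 0.5. If no coordinate
#' does, the single largest coordinate is selected (lowest index on ties),
#' so the subset is never empty.
#'
#' @param position numeric vector with coordinates in \[0, 1\].
#' @return a `feature_subset` list with `mask` (logical), `indices`
#'   (1-based), and `size`.
#' @export
binarize_position <- function(position) {
  mask <- position > 0.5
  if (!any(mask)) mask[which.max(position)] <- TRUE
  feature_subset(mask)
}

#' Construct a feature subset from a logical mask
#' @param mask logical inclusion vector over the features.
#' @return a `feature_subset` list.
#' @export
feature_subset <- function(mask) {
  mask <- as.logical(mask)
  if (!any(mask)) stop("a feature subset must contain at least one feature")
  structure(list(mask = mask, indices = which(mask), size = sum(mask)),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat(sprintf("feature_subset: %d of %d features (indices %s)\n",
              x$size, length(x$mask), paste(x$indices, collapse = ", ")))
  invisible(x)
}

# stratified fold assignment, deterministic in `seed`; RNG state of the
# caller is preserved
make_cv_folds <- function(labels, k, seed) {
  n <- length(labels)
  folds <- integer(n)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# pooled CV misclassification rate of the k-NN wrapper on the masked matrix
knn_cv_error <- function(values, labels, folds, k) {
  pred <- integer(length(labels))
  for (f in sort(unique(folds))) {
    te <- folds == f
    if (length(unique(labels[!te])) < 2L)
      stop("a training fold contains a single class; reduce cv_folds")
    pred[te] <- as.integer(as.character(
      class::knn(values[!te, , drop = FALSE], values[te, , drop = FALSE],
                 factor(labels[!te]), k = k)))
  }
  mean(pred != labels)
}

#' Wrapper fitness of a feature subset
#'
#' @param subset a [feature_subset()].
#' @param table a preprocessed [clinical_table()].
#' @param cfg a [fitness_config()].
#' @param folds optional precomputed fold assignment (as returned
#'   internally from the config seed); supplied by [select_features()] so
#'   every evaluation shares one stratification.
#' @return scalar cost `alpha * error + beta * size / d` in \[0, 1\].
#' @export
subset_fitness <- function(subset, table, cfg = fitness_config(),
                           folds = NULL) {
  stopifnot(inherits(subset, "feature_subset"),
            inherits(table, "clinical_table"))
  if (is.null(folds))
    folds <- make_cv_folds(table$labels, cfg$cv_folds, cfg$seed)
  err <- knn_cv_error(table$values[, subset$mask, drop = FALSE],
                      table$labels, folds, cfg$knn_k)
  cfg$alpha * err + cfg$beta * subset$size / table$d
}

#' Select features with the elite opposition-based squirrel search
#'
#' Runs the (EO-)SSA over the unit hypercube `[0, 1]^d`; each position is
#' binarized with [binarize_position()] and scored with
#' [subset_fitness()]. Fitness values are memoized per mask, since many
#' continuous positions map to the same subset.
#'
#' @param table a preprocessed [clinical_table()].
#' @param ssa_cfg an [ssa_config()] (its `dim`, `lower`, `upper` are forced
#'   to `d`, 0 and 1).
#' @param eobl_cfg an [eobl_config()].
#' @param fit_cfg a [fitness_config()].
#' @return list with `subset` (the best [feature_subset()], 1-based
#'   indices), `cost`, and the best-so-far `trace`.
#' @export
select_features <- function(table,
                            ssa_cfg = ssa_config(dim = table$d, n_iter = 50),
                            eobl_cfg = eobl_config(),
                            fit_cfg = fitness_config()) {
  stopifnot(inherits(table, "clinical_table"))
  ssa_cfg$dim <- table$d
  ssa_cfg$lower <- rep(0, table$d)
  ssa_cfg$upper <- rep(1, table$d)
  folds <- make_cv_folds(table$labels, fit_cfg$cv_folds, fit_cfg$seed)
  cache <- new.env(parent = emptyenv())
  objective <- function(position) {
    subset <- binarize_position(position)
    key <- paste(as.integer(subset$mask), collapse = "")
    got <- get0(key, envir = cache)
    if (!is.null(got)) return(got)
    val <- subset_fitness(subset, table, fit_cfg, folds)
    assign(key, val, envir = cache)
    val
  }
  res <- ssa_optimize(objective, ssa_cfg, eobl_cfg)
  list(subset = binarize_position(res$par), cost = res$value,
       trace = res$trace)
}

#' Brute-force best subset (oracle for small d)
#'
#' Enumerates all non-empty subsets and returns the minimum wrapper cost;
#' used as a lower-bound oracle in tests on small feature counts.
#'
#' @inheritParams select_features
#' @return list with `subset`, `cost`.
#' @export
best_subset_exhaustive <- function(table, fit_cfg = fitness_config()) {
  stopifnot(table$d <= 20)
  folds <- make_cv_folds(table$labels, fit_cfg$cv_folds, fit_cfg$seed)
  best <- NULL; best_cost <- Inf
  for (code in seq_len(2^table$d - 1L)) {
    mask <- as.logical(bitwAnd(code, 2^(seq_len(table$d) - 1L)))
    s <- feature_subset(mask)
    cost <- subset_fitness(s, table, fit_cfg, folds)
    if (cost < best_cost) { best_cost <- cost; best <- s }
  }
  list(subset = best, cost = best_cost)
}
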