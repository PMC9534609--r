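#' Confusion matrix for binary labels
#'
#' Positive class = presence of heart disease (label 1).
#'
#' @param truth,predicted binary vectors of equal length.
#' @return a `confusion_matrix` list with `tp`, `fn`, `fp`, `tn`.
#' @export
confusion <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted),
            all(truth %in% 0:1), all(predicted %in% 0:1))
  structure(list(tp = sum(truth == 1 & predicted == 1),
                 fn = sum(truth == 1 & predicted == 0),
                 fp = sum(truth == 0 & predicted == 1),
                 tn = sum(truth == 0 & predicted == 0)),
            class = "confusion_matrix")
}

#' Construct a confusion matrix from counts
#' @param tp,fn,fp,tn non-negative integer counts.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("presence", "absence"),
                              predicted = c("presence", "absence")))
  print(m)
  invisible(x)
}

# round half-up to `digits` decimals (matches report rendering; R's
# round() rounds half to even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' The six classification metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP),
#' accuracy (TP+TN)/n, F-score 2*prec*sens/(prec+sens), and the Matthews
#' correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)),
#' all expressed as percentages. A metric whose denominator vanishes is
#' reported as `NA` and flagged in the `"undefined"` attribute.
#'
#' @param cm a `confusion_matrix`.
#' @param digits decimals for the rendered values (full precision is kept
#'   when `digits = NULL`).
#' @return a one-row data.frame with columns `sensitivity`, `specificity`,
#'   `precision`, `accuracy`, `f_score`, `mcc`, in percent.
#' @export
metrics <- function(cm, digits = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  n <- tp + fn + fp + tn
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  acc <- safe_div(tp + tn, n)
  f <- if (is.na(sens) || is.na(prec) || sens + prec == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  out <- data.frame(sensitivity = sens, specificity = spec,
                    precision = prec, accuracy = acc, f_score = f,
                    mcc = mcc) * 100
  attr(out, "undefined") <- names(out)[is.na(unlist(out))]
  if (!is.null(digits)) out[] <- lapply(out, round_half_up, digits)
  out
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney formulation with midranks for ties: the probability that a
#' random positive scores above a random negative, counting ties as 1/2.
#'
#' @param truth binary labels (1 = positive).
#' @param scores positive-class scores.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(truth, scores) {
  stopifnot(length(truth) == length(scores), all(truth %in% 0:1))
  n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC requires both classes to be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average a set of metric rows
#'
#' Arithmetic mean of each metric column, rounded half-up to two decimals
#' (the convention used when averaging per-iteration report rows).
#'
#' @param rows data.frame of metric rows (percent scale).
#' @return a one-row data.frame of column means.
#' @export
average_metrics <- function(rows) {
  out <- as.data.frame(lapply(rows, function(col) {
    round_half_up(mean(col), 2)
  }))
  rownames(out) <- NULL
  out
}

# k-NN fold classifier for the evaluation harness
fold_classifier_knn <- function(k = 5) {
  function(train_table, test_table) {
    as.integer(as.character(class::knn(
      train_table$values, test_table$values,
      factor(train_table$labels), k = k)))
  }
}

subset_table <- function(table, rows = NULL, subset = NULL) {
  vals <- table$values
  mask <- table$missing_mask
  if (!is.null(subset)) {
    vals <- vals[, subset$mask, drop = FALSE]
    mask <- mask[, subset$mask, drop = FALSE]
  }
  if (!is.null(rows)) {
    vals <- vals[rows, , drop = FALSE]
    mask <- mask[rows, , drop = FALSE]
    labels <- table$labels[rows]
  } else labels <- table$labels
  clinical_table(vals, labels, missing_mask = mask)
}

#' Repeated cross-validated evaluation
#'
#' Runs `n_iterations` rounds; each round performs stratified k-fold
#' cross-validation with a distinct seed, pools the fold predictions into
#' one confusion matrix covering all n instances, and derives the six
#' metrics. The returned report carries one row per round plus the
#' average row.
#'
#' @param table a [clinical_table()] (imputed; see `normalize_per_fold`).
#' @param subset optional [feature_subset()] restricting the features.
#' @param classifier a function `(train_table, test_table) -> predicted
#'   labels`; defaults to a k-NN fold classifier. Use
#'   [acnn_lstm_fold_classifier()] for the neural classifier.
#' @param n_iterations number of repeated rounds (10).
#' @param cv_folds folds per round (10, stratified).
#' @param seed base seed; round i uses `seed + i`.
#' @param normalize_per_fold if TRUE, min-max parameters are fitted on the
#'   training folds only and applied to the held-out fold, avoiding
#'   leakage.
#' @return list with `rows` (n_iterations x 6 data.frame, 2-decimal
#'   percentages), `average` (1 x 6), and `confusions` (list of pooled
#'   `confusion_matrix` objects).
#' @export
run_iterations <- function(table, subset = NULL,
                           classifier = fold_classifier_knn(),
                           n_iterations = 10, cv_folds = 10, seed = 1,
                           normalize_per_fold = TRUE) {
  stopifnot(inherits(table, "clinical_table"))
  if (any(table$missing_mask))
    stop("impute missing values before evaluation")
  work <- subset_table(table, subset = subset)
  rows <- NULL
  confusions <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    folds <- make_cv_folds(work$labels, cv_folds, seed + it)
    pred <- integer(work$n)
    for (f in sort(unique(folds))) {
      te <- folds == f
      tr_tab <- subset_table(work, rows = !te)
      te_tab <- subset_table(work, rows = te)
      if (normalize_per_fold) {
        tr_tab <- normalize_table(tr_tab)
        te_tab <- apply_normalization(te_tab, attr(tr_tab, "norm_params"))
      }
      pred[te] <- classifier(tr_tab, te_tab)
    }
    cm <- confusion(work$labels, pred)
    confusions[[it]] <- cm
    rows <- rbind(rows, metrics(cm, digits = 2))
  }
  rownames(rows) <- paste0("iteration_", seq_len(n_iterations))
  list(rows = rows, average = average_metrics(rows),
       confusions = confusions)
}

#' Write a Table-2-style report CSV
#'
#' One row per iteration plus the average row, columns ordered
#' Sensitivity, Specificity, Precision, Accuracy, F-score, MCC.
#'
#' @param report the list returned by [run_iterations()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  tab <- rbind(report$rows, Average = report$average)
  tab <- cbind(iteration = rownames(tab), tab)
  names(tab) <- c("Iteration", "Sensitivity", "Specificity", "Precision",
                  "Accuracy", "F-score", "MCC")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
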