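test_that("confusion counts partition the sample", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unclass(cm)[c("tp", "fn", "fp", "tn")],
               list(tp = 2L, fn = 0L, fp = 0L, tn = 2L))
  cm2 <- confusion(c(1, 0), c(1, 1))
  expect_equal(cm2$tp, 1L); expect_equal(cm2$fp, 1L)
  set.seed(2)
  truth <- rbinom(100, 1, 0.4); pred <- rbinom(100, 1, 0.5)
  cm3 <- confusion(truth, pred)
  expect_equal(cm3$tp + cm3$fn + cm3$fp + cm3$tn, 100L)
})

test_that("metrics agree with a brute-force recomputation from label vectors", {
  set.seed(9)
  for (i in 1:200) {
    n <- sample(20:60, 1)
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    pred <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(truth)) < 2 || length(unique(pred)) < 2) next
    m <- metrics(confusion(truth, pred))
    # independent recomputation directly from the vectors
    expect_equal(m$sensitivity / 100, mean(pred[truth == 1] == 1))
    expect_equal(m$specificity / 100, mean(pred[truth == 0] == 0))
    expect_equal(m$precision / 100, mean(truth[pred == 1] == 1))
    expect_equal(m$accuracy / 100, mean(pred == truth))
    expect_equal(m$mcc / 100, suppressWarnings(cor(truth, pred)),
                 tolerance = 1e-12)
    p <- m$precision / 100; s <- m$sensitivity / 100
    expect_equal(m$f_score / 100, 2 * p * s / (p + s))
  }
})

test_that("MCC is symmetric under class swap and perfection scores 100", {
  cm <- confusion_counts(tp = 30, fn = 5, fp = 8, tn = 40)
  swapped <- confusion_counts(tp = 40, fn = 8, fp = 5, tn = 30)
  expect_equal(metrics(cm)$mcc, metrics(swapped)$mcc)
  perfect <- metrics(confusion_counts(tp = 10, fn = 0, fp = 0, tn = 10))
  expect_equal(unlist(perfect), rep(100, 6), ignore_attr = TRUE)
})

test_that("the accuracy identity holds to numerical precision", {
  set.seed(4)
  for (i in 1:50) {
    cm <- confusion_counts(tp = sample(1:50, 1), fn = sample(1:50, 1),
                           fp = sample(1:50, 1), tn = sample(1:50, 1))
    m <- metrics(cm)
    p <- cm$tp + cm$fn; nn <- cm$tn + cm$fp
    expect_equal(m$accuracy,
                 (m$sensitivity * p + m$specificity * nn) / (p + nn),
                 tolerance = 1e-12)
  }
})

test_that("degenerate confusion matrices flag undefined metrics", {
  m <- metrics(confusion_counts(tp = 0, fn = 0, fp = 3, tn = 7))
  expect_true(is.na(m$sensitivity))
  expect_true("sensitivity" %in% attr(m, "undefined"))
})

test_that("rank AUC matches the all-pairs oracle and handles ties", {
  set.seed(13)
  truth <- rbinom(200, 1, 0.5)
  scores <- round(rnorm(200), 1)  # rounding forces ties
  auc <- roc_auc(truth, scores)
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  pairs <- outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b))
  expect_equal(auc, mean(pairs), tolerance = 1e-12)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(3, 4, 1, 2)), 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), rep(2, 4)), 0.5)
})

test_that("rank AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(21)
  truth <- rbinom(150, 1, 0.45)
  scores <- rnorm(150) + truth
  expect_equal(roc_auc(truth, scores),
               as.numeric(pROC::auc(pROC::roc(truth, scores,
                                              quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("averaging the printed per-iteration sensitivities gives the printed mean", {
  sens <- c(98.17, 98.17, 97.56, 98.17, 96.95, 100.00, 98.17, 100.00,
            98.17, 96.95)
  avg <- average_metrics(data.frame(sensitivity = sens))
  expect_equal(avg$sensitivity, 98.23)
})

test_that("rounding is half-up as in printed reports", {
  expect_equal(cardiofs:::round_half_up(97.125, 2), 97.13)
  expect_equal(cardiofs:::round_half_up(97.124, 2), 97.12)
  expect_equal(cardiofs:::round_half_up(-97.125, 2), -97.13)
})

test_that("repeated CV pools fold predictions over all instances", {
  tab <- separable_table(n = 60, d = 4, k = 2, effect = 2.5, seed = 12)
  rep3 <- run_iterations(tab, n_iterations = 3, cv_folds = 5, seed = 4)
  expect_equal(nrow(rep3$rows), 3L)
  for (cm in rep3$confusions)
    expect_equal(cm$tp + cm$fn + cm$fp + cm$tn, 60L)
  one <- run_iterations(tab, n_iterations = 1, cv_folds = 5, seed = 4)
  expect_equal(unlist(one$average), unlist(one$rows[1, ]),
               ignore_attr = TRUE)
  # determinism
  rep3b <- run_iterations(tab, n_iterations = 3, cv_folds = 5, seed = 4)
  expect_identical(rep3$rows, rep3b$rows)
})

test_that("the report CSV mirrors the six-metric layout", {
  tab <- separable_table(n = 40, d = 3, k = 2, effect = 2.5, seed = 14)
  rep2 <- run_iterations(tab, n_iterations = 2, cv_folds = 4, seed = 1)
  path <- tempfile(fileext = ".csv")
  write_report_csv(rep2, path)
  got <- read.csv(path, check.names = FALSE)
  expect_equal(names(got), c("Iteration", "Sensitivity", "Specificity",
                             "Precision", "Accuracy", "F-score", "MCC"))
  expect_equal(nrow(got), 3L)  # 2 iterations + average
})
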