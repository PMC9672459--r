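test_that("metrics match hand-evaluated confusion matrices", {
  m <- compute_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(c(m$acc, m$sn, m$sp, m$mcc), c(1, 1, 1, 1))
  m2 <- compute_metrics(1, 1, 1, 1)
  expect_equal(m2$acc, 0.5)
  expect_equal(m2$mcc, 0)
  m3 <- compute_metrics(90, 80, 20, 10)
  expect_equal(m3$sn, 0.9)
  expect_equal(m3$sp, 0.8)
  expect_equal(m3$acc, 0.85)
  expect_equal(m3$mcc, 0.7035, tolerance = 1e-4)
  expect_equal(m3$precision, 90 / 110)
  expect_equal(m3$recall, 0.9)
  expect_error(compute_metrics(0, 0, 0, 0), "zero")
})

test_that("MCC with a vanishing denominator is defined as 0", {
  expect_equal(compute_metrics(0, 5, 0, 5)$mcc, 0)
  expect_equal(compute_metrics(3, 0, 7, 0)$mcc, 0)
})

test_that("metrics agree with the counting oracle on random outcomes", {
  withr::local_seed(31)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    y <- stats::rbinom(n, 1, 0.5)
    pred <- stats::rbinom(n, 1, 0.5)
    if (sum(y) == n || sum(y) == 0) next
    got <- compute_metrics(confusion_counts(y, pred))
    want <- oracle_metrics(y, pred)
    for (f in c("acc", "sn", "sp", "mcc", "precision", "recall"))
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
  }
})

test_that("AUROC matches hand-derived values and handles ties", {
  expect_equal(roc_curve(c(0, 0, 1, 1), c(0.1, 0.6, 0.4, 0.8))$auroc, 0.75)
  expect_equal(roc_curve(c(0, 1, 0, 1), c(0, 1, 0, 1))$auroc, 1.0)
  expect_equal(roc_curve(c(0, 1, 0, 1), rep(0.5, 4))$auroc, 0.5)
  expect_error(roc_curve(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("ROC points are monotone and span (0,0) to (1,1)", {
  withr::local_seed(5)
  y <- stats::rbinom(50, 1, 0.4)
  sc <- stats::runif(50) + 0.3 * y
  r <- roc_curve(y, sc)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
})

test_that("AUROC equals the pairwise oracle on exhaustive small inputs", {
  withr::local_seed(77)
  for (n in 2:12) {
    scores <- round(stats::runif(n), 2)   # rounding forces occasional ties
    for (code in seq_len(2^n - 2)) {
      y <- as.integer(intToBits(code))[1:n]
      expect_equal(roc_curve(y, scores)$auroc, oracle_auroc(y, scores),
                   tolerance = 1e-12)
    }
  }
})

test_that("AUROC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(12)
  for (rep in 1:10) {
    y <- stats::rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    sc <- stats::runif(40)
    ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_curve(y, sc)$auroc, ref, tolerance = 1e-12)
  }
})

test_that("stratified folds partition the data evenly and reproducibly", {
  y <- rep(c(0, 1), c(60, 40))
  f <- stratified_folds(y, 5, seed = 3)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f, y) %in% c(8, 12)))
  expect_identical(f, stratified_folds(y, 5, seed = 3))
  expect_error(stratified_folds(rep(c(0, 1), c(3, 50)), 5), "fewer than k")
  expect_error(stratified_folds(y, 1), "k must be")
})

test_that("cross-validation folds are disjoint, exhaustive and averaged", {
  b_x <- matrix(stats::rnorm(200), 100, 2)
  b_x[51:100, ] <- b_x[51:100, ] + 4
  y <- rep(c(0, 1), each = 50)
  trainer <- function(x, yy)
    baseline_fit(baseline_spec("logistic_regression"), x, yy)
  cv <- kfold_cv(b_x, y, trainer, k = 5, seed = 2)
  expect_equal(nrow(cv$folds), 5)
  expect_equal(length(cv$fold_id), 100)
  expect_equal(sort(unique(cv$fold_id)), 1:5)
  expect_equal(unname(cv$mean[["acc"]]), mean(cv$folds$acc))
  expect_gte(cv$mean[["acc"]], 0.95)
  cv2 <- kfold_cv(b_x, y, trainer, k = 5, seed = 2)
  expect_equal(cv$folds, cv2$folds)
})

test_that("evaluate_scores combines thresholded metrics with AUROC", {
  y <- c(0, 0, 1, 1)
  m <- evaluate_scores(y, c(0.2, 0.6, 0.7, 0.9))
  expect_equal(m$acc, 0.75)
  expect_equal(m$auroc, 1.0)
  expect_equal(m$counts, list(TP = 2L, TN = 1L, FP = 1L, FN = 0L))
})
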