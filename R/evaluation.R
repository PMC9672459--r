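#' Confusion counts from binary outcomes
#'
#' @param y_true true labels (0/1 numeric or two-level factor, second level
#'   positive).
#' @param y_pred predicted labels in the same form.
#' @return List with integer fields `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  yt <- as_binary_labels(if (is.factor(y_true)) y_true else as.numeric(y_true))$y01
  yp <- as_binary_labels(if (is.factor(y_pred)) y_pred else as.numeric(y_pred))$y01
  if (length(yt) != length(yp)) stop("length mismatch")
  list(TP = sum(yt == 1 & yp == 1), TN = sum(yt == 0 & yp == 0),
       FP = sum(yt == 0 & yp == 1), FN = sum(yt == 1 & yp == 0))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall), specificity, Matthews correlation
#' coefficient, and precision:
#' \deqn{Acc = (TP+TN)/(TP+TN+FP+FN), \quad Sn = TP/(TP+FN), \quad
#'       Sp = TN/(TN+FP)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'       \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' MCC is defined as 0 when its denominator vanishes. An undefined ratio
#' (e.g. sensitivity with no positives) yields `NaN`.
#'
#' @param counts a list with `TP`, `TN`, `FP`, `FN` (from
#'   [confusion_counts()]), or the `TP` count if the four counts are passed
#'   positionally.
#' @param tn,fp,fn remaining counts when passed positionally.
#' @return A list of class `metrics_report` with fields `acc`, `sn`, `sp`,
#'   `mcc`, `precision`, `recall` and the input `counts`.
#' @export
compute_metrics <- function(counts, tn = NULL, fp = NULL, fn = NULL) {
  if (is.numeric(counts) && length(counts) == 1)
    counts <- list(TP = counts, TN = tn, FP = fp, FN = fn)
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  if (total == 0) stop("all confusion counts are zero")
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  structure(list(
    acc = (tp + tn) / total,
    sn = tp / (tp + fn),
    sp = tn / (tn + fp),
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den,
    precision = tp / (tp + fp),
    recall = tp / (tp + fn),
    counts = list(TP = tp, TN = tn, FP = fp, FN = fn)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("acc %.4f  sn %.4f  sp %.4f  mcc %.4f  precision %.4f",
              x$acc, x$sn, x$sp, x$mcc, x$precision))
  if (!is.null(x$auroc)) cat(sprintf("  auroc %.4f", x$auroc))
  cat("\n")
  invisible(x)
}

#' ROC curve and AUROC
#'
#' Operating points sweep the decision threshold over the observed scores
#' (score >= threshold predicts positive); the curve is returned as
#' monotone (FPR, TPR) points. AUROC is computed by the rank (Mann-Whitney)
#' statistic, counting ties as half, which equals the trapezoidal area under
#' the tie-aware curve.
#'
#' @param y_true binary labels (0/1 or two-level factor, second level
#'   positive).
#' @param scores numeric scores, higher = more positive.
#' @return List of class `roc_result` with `points` (data frame
#'   `threshold`, `fpr`, `tpr`) and `auroc`.
#' @export
roc_curve <- function(y_true, scores) {
  yt <- as_binary_labels(if (is.factor(y_true)) y_true else
    as.numeric(y_true))$y01
  if (length(yt) != length(scores)) stop("length mismatch")
  n1 <- sum(yt == 1); n0 <- sum(yt == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  auroc <- (sum(rank(scores)[yt == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    pred <- as.numeric(scores >= t)
    c(fpr = sum(pred == 1 & yt == 0) / n0, tpr = sum(pred == 1 & yt == 1) / n1)
  }, numeric(2)))
  structure(list(points = data.frame(threshold = thr, fpr = pts[, "fpr"],
                                     tpr = pts[, "tpr"]),
                 auroc = auroc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> ", nrow(x$points), " operating points, AUROC ",
      sprintf("%.4f", x$auroc), "\n", sep = "")
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "s",
                 xlab = "false positive rate", ylab = "true positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Metrics from scores
#'
#' Thresholds scores at `threshold`, computes the confusion-count metrics
#' and adds AUROC.
#'
#' @inheritParams roc_curve
#' @param threshold decision threshold (default 0.5).
#' @return A `metrics_report` with an `auroc` field.
#' @export
evaluate_scores <- function(y_true, scores, threshold = 0.5) {
  yt <- as_binary_labels(if (is.factor(y_true)) y_true else
    as.numeric(y_true))$y01
  rep <- compute_metrics(confusion_counts(yt, as.numeric(scores >= threshold)))
  rep$auroc <- roc_curve(yt, scores)$auroc
  rep
}

#' Stratified fold assignment
#'
#' @param y labels (any type with at least `k` members per class).
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1..k`; within each class, fold
#'   sizes differ by at most one.
#' @export
stratified_folds <- function(y, k = 5, seed = 1) {
  if (k < 2) stop("k must be >= 2")
  cts <- table(y)
  if (any(cts < k))
    stop("class '", names(cts)[which(cts < k)[1]], "' has fewer than k = ",
         k, " members")
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in names(cts)) {
      idx <- which(y == cl)
      folds[idx] <- rep_len(sample.int(k), length(idx))[sample.int(length(idx))]
    }
  })
  folds
}

#' Stratified k-fold cross-validation
#'
#' Trains `trainer` on each training split and scores the held-out fold;
#' per-fold metrics (including AUROC) are retained and summarized by their
#' unweighted mean. Fold assignment is stratified and deterministic given
#' `seed`.
#'
#' @param x features: an `n x p` matrix, or an `n x rows x channels` array
#'   for the CNN.
#' @param y binary labels (0/1 or two-level factor).
#' @param trainer `function(x_train, y_train)` returning a fitted object
#'   whose `predict(fit, x)` yields positive-class probabilities.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param threshold decision threshold (default 0.5).
#' @return List of class `cv_report`: `folds` (data frame of per-fold
#'   metrics), `mean` (named numeric vector), `fold_id` (assignment vector).
#' @export
kfold_cv <- function(x, y, trainer, k = 5, seed = 1, threshold = 0.5) {
  lab <- as_binary_labels(y)
  fold_id <- stratified_folds(lab$y01, k, seed)
  take <- function(x, idx)
    if (length(dim(x)) == 3) x[idx, , , drop = FALSE]
    else x[idx, , drop = FALSE]
  rows <- lapply(seq_len(k), function(f) {
    tr <- fold_id != f
    fit <- trainer(take(x, which(tr)), if (is.factor(y)) y[tr] else lab$y01[tr])
    sc <- predict(fit, take(x, which(!tr)))
    m <- evaluate_scores(lab$y01[!tr], sc, threshold)
    data.frame(fold = f, acc = m$acc, sn = m$sn, sp = m$sp, mcc = m$mcc,
               precision = m$precision, recall = m$recall, auroc = m$auroc)
  })
  folds <- do.call(rbind, rows)
  structure(list(folds = folds,
                 mean = colMeans(folds[, -1, drop = FALSE]),
                 fold_id = fold_id),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", nrow(x$folds), "-fold cross-validation\n", sep = "")
  print(round(x$mean, 4))
  invisible(x)
}
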