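## Confusion-matrix metrics, ROC/AUC, and k-fold cross-validation.

#' Tally a 2x2 confusion matrix
#'
#' @param labels True labels (logical, 0/1, or `"positive"`/`"negative"`).
#' @param calls Predicted labels, same encoding and length.
#' @return List of class `"confusion_counts"` with `tp`, `fn`, `tn`, `fp`.
#' @export
confusion <- function(labels, calls) {
  l <- as_pm1(labels) > 0
  c <- as_pm1(calls) > 0
  if (length(l) != length(c)) stop("labels and calls differ in length")
  structure(list(tp = sum(l & c), fn = sum(l & !c),
                 tn = sum(!l & !c), fp = sum(!l & c)),
            class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and Matthews correlation
#'
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `Acc = (TP+TN)/total`,
#' `MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`.
#' A zero denominator yields `NaN` with a warning for the ratio measures
#' and 0 by convention for the MCC.
#'
#' @param counts A `"confusion_counts"` (or list with `tp`, `fn`, `tn`,
#'   `fp`).
#' @return List of class `"palm_metrics"`: `Sn`, `Sp`, `Acc`, `MCC`.
#' @export
classification_metrics <- function(counts) {
  tp <- as.double(counts$tp); fn <- as.double(counts$fn)
  tn <- as.double(counts$tn); fp <- as.double(counts$fp)
  total <- tp + fn + tn + fp
  if (total == 0) stop("empty confusion matrix")
  ratio <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)"); NaN }
    else num / den
  }
  mcc_den <- sqrt((tp + fn) * (tn + fp) * (tp + fp) * (tn + fn))
  structure(list(Sn = ratio(tp, tp + fn, "sensitivity"),
                 Sp = ratio(tn, tn + fp, "specificity"),
                 Acc = (tp + tn) / total,
                 MCC = if (mcc_den == 0) 0 else (tp * tn - fn * fp) / mcc_den),
            class = "palm_metrics")
}

#' @export
print.palm_metrics <- function(x, ...) {
  cat(sprintf("Sn = %.3f  Sp = %.3f  Acc = %.3f  MCC = %.3f",
              x$Sn, x$Sp, x$Acc, x$MCC))
  if (!is.null(x$AUC)) cat(sprintf("  AUC = %.3f", x$AUC))
  cat("\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC is the probability that a random positive outscores a random
#' negative, with ties counted one half (the Mann-Whitney statistic,
#' equal to trapezoidal integration of the ROC curve).
#'
#' @param labels True labels (both classes must be present).
#' @param scores Numeric scores, higher = more positive.
#' @return List with `auc` and `curve` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(labels, scores) {
  y <- as_pm1(labels) > 0
  if (length(y) != length(scores)) stop("labels and scores differ in length")
  n1 <- as.double(sum(y)); n0 <- as.double(sum(!y))
  if (n1 == 0 || n0 == 0) stop("both classes are required for a ROC curve")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(y[ord]); fp <- cumsum(!y[ord])
  last <- !duplicated(scores[ord], fromLast = TRUE)  # one point per threshold
  curve <- data.frame(threshold = scores[ord][last],
                      fpr = fp[last] / n0, tpr = tp[last] / n1)
  curve <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), curve)
  list(auc = auc, curve = curve)
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' For each fold the complete pipeline - MDD motif tree, first-layer
#' subgroup SVMs and the stacking SVM - is re-learned on the remaining
#' folds (no leakage), the held-out fold is scored, and all held-out
#' predictions are pooled into a single estimate.
#'
#' @inheritParams train_two_layer
#' @param k Number of folds (default 5). `k` equal to the dataset size
#'   gives leave-one-out.
#' @param threshold Decision threshold for the pooled confusion matrix.
#' @return List with `metrics` (including `AUC`), `roc`, `counts`, and
#'   `predictions` (data.frame with fold, label, probability).
#' @export
kfold_cv <- function(dataset, k = 5L, recipe = c("aac", "pssm"),
                     scheme = aa_group_scheme(), mdd_cfg = mdd_config(),
                     params = svm_params(), meta_params = svm_params(),
                     ratio = 8, crossfit_folds = 5L, seed = 1L,
                     asa_table = NULL, pssm = NULL, threshold = 0.5) {
  stopifnot(inherits(dataset, "palm_fragments"), k >= 2L)
  y <- dataset$label == "positive"
  n <- nrow(dataset)
  if (k > n) stop("more folds than fragments")
  assign <- if (k == n) seq_len(n) else stratified_folds(y, k, seed)
  prob <- numeric(n)
  for (f in seq_len(k)) {
    tr <- which(assign != f)
    if (length(unique(y[tr])) < 2L) {
      stop("training split for fold ", f, " lacks a class; dataset too small")
    }
    train <- dataset[tr, , drop = FALSE]
    attr(train, "n") <- attr(dataset, "n"); class(train) <- class(dataset)
    model <- train_two_layer(train, recipe = recipe, scheme = scheme,
                             mdd_cfg = mdd_cfg, params = params,
                             meta_params = meta_params, ratio = ratio,
                             crossfit_folds = crossfit_folds,
                             seed = derive_seed(seed, f),
                             asa_table = asa_table, pssm = pssm,
                             threshold = threshold)
    te <- which(assign == f)
    prob[te] <- predict_two_layer(model, dataset$fragment[te])
  }
  counts <- confusion(y, prob >= threshold)
  metrics <- classification_metrics(counts)
  roc <- roc_auc(y, prob)
  metrics$AUC <- roc$auc
  list(metrics = metrics, roc = roc, counts = counts,
       predictions = data.frame(fold = assign, label = dataset$label,
                                probability = prob,
                                stringsAsFactors = FALSE))
}
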