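# Independent oracles, deliberately written as naive loops so they share
# no code path with the package implementations they check.

# Chi-square of a count matrix, cell by cell.
chi2_oracle <- function(tab) {
  total <- sum(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  acc <- 0
  for (m in seq_len(nrow(tab))) {
    for (n in seq_len(ncol(tab))) {
      e <- rs[m] * cs[n] / total
      if (e > 0) acc <- acc + (tab[m, n] - e)^2 / e
    }
  }
  acc
}

# Sn/Sp/Acc/MCC straight from the definitions.
metrics_oracle <- function(tp, fn, tn, fp) {
  den <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)
  list(Sn = tp / (tp + fn), Sp = tn / (tn + fp),
       Acc = (tp + tn) / (tp + fn + tn + fp),
       MCC = if (den == 0) 0 else (tp * tn - fn * fp) / den)
}

# AUC by exhaustive pair counting, ties worth one half.
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1 | labels == TRUE | labels == "positive"]
  neg <- scores[!(labels == 1 | labels == TRUE | labels == "positive")]
  acc <- 0
  for (p in pos) for (q in neg) {
    acc <- acc + (p > q) + 0.5 * (p == q)
  }
  acc / (length(pos) * length(neg))
}

# Two-proportion z-test p-value, direct formula.
ztest_oracle <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  if (se == 0) return(1)
  2 * pnorm(-abs((p1 - p2) / se))
}

# KKT optimality check for the C-SVC dual solved by svm_train: with
# f_i the decision value at training point i,
#   alpha_i = 0      -> y_i f_i >= 1 - tol
#   0 < alpha_i < C  -> |y_i f_i - 1| <= tol
#   alpha_i = C      -> y_i f_i <= 1 + tol
svm_kkt_violation <- function(x, y, model) {
  f <- svm_decision(model, x)
  yy <- ifelse(y, 1, -1)
  # recover alpha on training rows from the stored sv coefficients
  alpha <- rep(0, nrow(x))
  # match support vectors back to training rows
  for (s in seq_len(nrow(model$sv_x))) {
    hit <- which(apply(x, 1, function(r) all(r == model$sv_x[s, ])))[1]
    alpha[hit] <- abs(model$coef[s])
  }
  m <- yy * f
  C <- model$cost
  viol <- numeric(0)
  viol <- c(viol,  (1 - m)[alpha < 1e-8])              # should be <= tol
  viol <- c(viol, abs(m - 1)[alpha > 1e-8 & alpha < C - 1e-8])
  viol <- c(viol,  (m - 1)[alpha > C - 1e-8])
  max(c(0, viol))
}
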