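#' Area under the ROC curve (rank form)
#'
#' AUC computed as the Mann-Whitney U statistic divided by
#' `n_case * n_control`, with tied scores counted half. Used in the
#' bootstrap and permutation loops; ROC curves and DeLong confidence
#' intervals use pROC (see [roc_summary()]).
#'
#' @param scores numeric scores, higher = more case-like.
#' @param labels binary labels (1 = case, 0 = control).
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal operating threshold
#'
#' Scans thresholds midway between adjacent distinct scores (plus the
#' extremes) and returns the one maximizing J = sensitivity +
#' specificity - 1, classifying `score >= threshold` as positive. Ties in
#' J are broken toward higher sensitivity, then toward the lower
#' threshold.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = case).
#' @return The threshold (numeric scalar).
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  sens <- vapply(cand, function(t) sum(scores >= t & labels == 1L) / n1, 0)
  spec <- vapply(cand, function(t) sum(scores < t & labels == 0L) / n0, 0)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[order(-sens[best], cand[best])][1L]
  cand[best]
}

#' Threshold classification metrics
#'
#' Sensitivity, specificity, accuracy and F1 for the rule
#' `score >= threshold` => positive. F1 is `2TP / (2TP + FP + FN)` and 0
#' when that denominator is 0.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = case).
#' @param threshold operating threshold.
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy`,
#'   `f1`.
#' @export
classification_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L); fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L); fp <- sum(pred == 1L & labels == 0L)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  c(sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(labels),
    f1 = f1)
}

#' ROC summary with DeLong confidence interval
#'
#' Full ROC via pROC, AUC with a 95% DeLong CI, and sensitivity /
#' specificity at the Youden-optimal operating point.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = case).
#' @return A `roc_summary` list: `auc`, `ci` (low, high), `sensitivity`,
#'   `specificity`, `threshold`, `roc` (the pROC object).
#' @export
roc_summary <- function(scores, labels) {
  roc <- pROC::roc(response = as.integer(labels), predictor = as.numeric(scores),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(roc, method = "delong"))
  thr <- youden_threshold(scores, labels)
  cm <- classification_metrics(scores, labels, thr)
  structure(list(auc = as.numeric(pROC::auc(roc)),
                 ci = c(low = ci[1], high = ci[3]),
                 sensitivity = unname(cm["sensitivity"]),
                 specificity = unname(cm["specificity"]),
                 threshold = thr, roc = roc),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), sens %.2f / spec %.2f at Youden threshold\n",
              x$auc, x$ci[1], x$ci[2], x$sensitivity, x$specificity))
  invisible(x)
}
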