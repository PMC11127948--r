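#' Regression error metrics
#'
#' Root-mean-square error and mean absolute error, in the units of the
#' target (clinical-score points here).
#'
#' @param y_true,y_pred Equal-length finite numeric vectors.
#' @return A single number.
#' @export
rmse <- function(y_true, y_pred) {
  check_reg_input(y_true, y_pred)
  sqrt(mean((y_true - y_pred)^2))
}

#' @rdname rmse
#' @export
mae <- function(y_true, y_pred) {
  check_reg_input(y_true, y_pred)
  mean(abs(y_true - y_pred))
}

check_reg_input <- function(y_true, y_pred) {
  if (length(y_true) == 0L) abort("empty input")
  if (length(y_true) != length(y_pred)) abort("length mismatch")
  if (any(!is.finite(y_true)) || any(!is.finite(y_pred))) {
    abort("inputs must be finite")
  }
}

as_binary_labels <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    lv <- sort(unique(as.character(labels)))
    if (all(lv %in% c("pMCI", "sMCI"))) {
      labels <- as.integer(labels == "pMCI")
    } else {
      abort("labels must be 0/1 or pMCI/sMCI")
    }
  }
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    abort("labels must be binary (0/1, with 1 = positive class)")
  }
  labels
}

#' Thresholded classification metrics
#'
#' Standard confusion-matrix metrics at a decision threshold. The positive
#' class is progressive MCI (label 1 or `"pMCI"`). Undefined ratios (e.g.
#' precision with no predicted positives) are returned as `NA` together
#' with a `note` naming the zero denominator — they are never silently 0.
#'
#' @param labels Binary labels (0/1 or sMCI/pMCI factors).
#' @param scores Predicted positive-class probabilities or scores.
#' @param threshold Decision threshold on `scores` (default 0.5).
#' @return A list with `acc`, `pre`, `rec`, `f1`, the confusion counts
#'   (`tp`, `fp`, `fn`, `tn`) and `note`.
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as_binary_labels(labels)
  if (length(labels) != length(scores)) abort("length mismatch")
  if (any(!is.finite(scores))) abort("scores must be finite")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  note <- character(0)
  pre <- if (tp + fp == 0L) {
    note <- c(note, "precision undefined: no predicted positives")
    NA_real_
  } else tp / (tp + fp)
  rec <- if (tp + fn == 0L) {
    note <- c(note, "recall undefined: no true positives in labels")
    NA_real_
  } else tp / (tp + fn)
  f1 <- if (is.na(pre) || is.na(rec) || pre + rec == 0) {
    note <- c(note, "F1 undefined")
    NA_real_
  } else 2 * pre * rec / (pre + rec)
  list(acc = (tp + tn) / length(labels), pre = pre, rec = rec, f1 = f1,
       confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
       note = if (length(note)) note else NULL)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over the unique scores (ties grouped at a
#' single threshold, giving the step-function convention) and integrates
#' the curve by the trapezoid rule. The resulting AUC equals the
#' Mann-Whitney pair statistic with ties counted one half.
#'
#' @inheritParams classification_metrics
#' @return A list with `roc` (a tibble of `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as_binary_labels(labels)
  if (length(labels) != length(scores)) abort("length mismatch")
  if (any(!is.finite(scores))) abort("scores must be finite")
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) {
    abort("AUC undefined: both classes must be present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  keep <- c(s[-length(s)] != s[-1], TRUE) # last index of each tie group
  tpr <- c(0, cumsum(l)[keep] / np)
  fpr <- c(0, cumsum(1 - l)[keep] / nn)
  thr <- c(Inf, s[keep])
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc)
}
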