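## Confusion-matrix metrics and ROC AUC.

#' Confusion matrix from predicted probabilities
#'
#' A peptide is called ACP when `P(ACP) >= threshold` (a probability exactly
#' at the threshold counts as positive).
#'
#' @param scores Numeric vector of `P(ACP)` values.
#' @param labels Binary labels (1 = ACP).
#' @param threshold Decision threshold, default 0.5.
#' @return A one-row tibble with integer columns `tp`, `fn`, `fp`, `tn`.
#' @export
#' @examples
#' confusion_matrix(c(0.9, 0.2, 0.8, 0.1), c(1, 1, 0, 0))
confusion_matrix <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    abort_validation("scores and labels must have equal length")
  }
  if (!all(labels %in% c(0L, 1L))) {
    abort_validation("labels must be binary 0/1")
  }
  pred <- as.integer(scores >= threshold)
  tibble::tibble(
    tp = sum(pred == 1L & labels == 1L),
    fn = sum(pred == 0L & labels == 1L),
    fp = sum(pred == 1L & labels == 0L),
    tn = sum(pred == 0L & labels == 0L)
  )
}

#' Threshold metrics from a confusion matrix
#'
#' Accuracy, sensitivity and specificity as percentages, and the Matthews
#' correlation coefficient:
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' MCC is defined as 0 whenever a factor of the denominator is 0 (so a
#' degenerate fold cannot poison a grid search with NaN).
#'
#' @param cm A one-row data frame with columns `tp`, `fn`, `fp`, `tn` (e.g.
#'   from [confusion_matrix()]), or a named numeric vector with those names.
#' @return A one-row tibble with columns `acc`, `sen`, `spc` (percent) and
#'   `mcc`.
#' @export
#' @examples
#' classification_metrics(data.frame(tp = 152, fn = 20, fp = 46, tn = 126))
classification_metrics <- function(cm) {
  if (!is.data.frame(cm)) cm <- tibble::as_tibble(as.list(cm))
  tp <- as.numeric(cm$tp); fn <- as.numeric(cm$fn)
  fp <- as.numeric(cm$fp); tn <- as.numeric(cm$tn)
  total <- tp + fn + fp + tn
  if (total == 0) abort_validation("empty confusion matrix")
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  tibble::tibble(
    acc = 100 * (tp + tn) / total,
    sen = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    spc = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    mcc = if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  )
}

#' ROC AUC (Mann-Whitney statistic)
#'
#' Area under the ROC curve computed as the Mann-Whitney concordance
#' probability: the fraction of (positive, negative) pairs in which the
#' positive scores higher, counting ties as 1/2. Computed from ranks, so it
#' is invariant under any strictly monotone transform of the scores.
#'
#' @inheritParams confusion_matrix
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort_validation("scores and labels must have equal length")
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort_validation("roc_auc() needs both classes present")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' @inheritParams confusion_matrix
#' @return A tibble with columns `threshold`, `fpr`, `tpr`, ordered from the
#'   (0, 0) to the (1, 1) corner.
#' @export
roc_curve <- function(scores, labels) {
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L) {
    abort_validation("roc_curve() needs both classes present")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- lapply(thr, function(th) {
    pred <- scores >= th
    c(fpr = sum(pred & labels == 0L) / sum(labels == 0L),
      tpr = sum(pred & labels == 1L) / sum(labels == 1L))
  })
  out <- tibble::as_tibble(do.call(rbind, pts))
  out$threshold <- thr
  structure(out[c("threshold", "fpr", "tpr")], class = c("acp_roc", class(out)))
}

#' Full evaluation of scored predictions
#'
#' Convenience wrapper combining [confusion_matrix()],
#' [classification_metrics()] and [roc_auc()].
#'
#' @inheritParams confusion_matrix
#' @return One-row tibble: `acc`, `sen`, `spc`, `mcc`, `auc`, `tp`, `fn`,
#'   `fp`, `tn`, `n`.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5) {
  cm <- confusion_matrix(scores, labels, threshold)
  dplyr::bind_cols(
    classification_metrics(cm),
    tibble::tibble(auc = roc_auc(scores, labels)),
    cm,
    tibble::tibble(n = length(scores))
  )
}
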