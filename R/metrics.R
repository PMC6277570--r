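#' Confusion counts at a decision threshold
#'
#' A molecule is called positive when its predicted probability is
#' greater than or equal to the threshold (ties count as positive).
#'
#' @param labels Binary 0/1 truth vector.
#' @param probabilities Predicted positive-class probabilities in
#'   `[0, 1]`.
#' @param threshold Decision threshold, default 0.5.
#' @return A one-row tibble with integer columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(labels, probabilities, threshold = 0.5) {
  labels <- .check_labels(labels, "labels")
  if (length(labels) != length(probabilities)) {
    abort("labels and probabilities differ in length")
  }
  if (anyNA(probabilities) || any(probabilities < 0 | probabilities > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  call_pos <- probabilities >= threshold
  tibble(
    tp = sum(call_pos & labels == 1L),
    tn = sum(!call_pos & labels == 0L),
    fp = sum(call_pos & labels == 0L),
    fn = sum(!call_pos & labels == 1L)
  )
}

#' Accuracy, sensitivity, specificity and Matthews correlation
#'
#' Computes the four threshold-based evaluation indexes from confusion
#' counts:
#' \deqn{ACC = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{SE  = TP/(TP+FN), \quad SP = TN/(TN+FP)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' MCC is reported as 0 when any factor of its denominator is zero (the
#' usual convention for degenerate tables); the square root is evaluated
#' in log space so very large counts cannot overflow. When there are no
#' positives at all (TP + FN = 0), sensitivity is undefined and reported
#' as `NA` with a warning — deliberately distinct from a sensitivity of
#' zero. Specificity is treated symmetrically.
#'
#' @param counts A one-row tibble or list with `tp`, `tn`, `fp`, `fn`.
#' @return A one-row tibble with `acc`, `se`, `sp`, `mcc`.
#' @export
classification_scores <- function(counts) {
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  total <- tp + tn + fp + fn
  if (total <= 0) abort("empty confusion table")
  acc <- (tp + tn) / total
  if (tp + fn == 0) {
    warn("no positive samples: sensitivity is undefined (NA)")
    se <- NA_real_
  } else {
    se <- tp / (tp + fn)
  }
  if (tn + fp == 0) {
    warn("no negative samples: specificity is undefined (NA)")
    sp <- NA_real_
  } else {
    sp <- tn / (tn + fp)
  }
  factors <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(factors == 0)) {
    mcc <- 0
  } else {
    num <- tp * tn - fp * fn
    mcc <- sign(num) * exp(log(abs(num)) - 0.5 * sum(log(factors)))
    if (num == 0) mcc <- 0
  }
  tibble(acc = acc, se = se, sp = sp, mcc = mcc)
}

#' Area under the ROC curve (rank statistic)
#'
#' Computed as the normalized Mann-Whitney U statistic: the fraction of
#' (positive, negative) pairs in which the positive molecule receives
#' the higher score, with tied scores contributing 1/2. Equivalent to
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param labels Binary 0/1 truth vector containing both classes.
#' @param probabilities Numeric scores (any monotone transform of
#'   probabilities gives the same value).
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(labels, probabilities) {
  labels <- .check_labels(labels, "labels")
  if (length(labels) != length(probabilities)) {
    abort("labels and probabilities differ in length")
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("AUC requires both classes to be present")
  }
  r <- rank(probabilities)   # midranks handle ties
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Five-index evaluation report
#'
#' Bundles the confusion counts at the given threshold with the five
#' standard indexes (ACC, SE, SP, MCC, AUC) into one row, the unit in
#' which all cross-validation and validation results are reported.
#'
#' @inheritParams confusion_counts
#' @return A one-row `eval_report` tibble with columns `tp`, `tn`, `fp`,
#'   `fn`, `acc`, `se`, `sp`, `mcc`, `auc`, `threshold`.
#' @examples
#' evaluate_predictions(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
#' @export
evaluate_predictions <- function(labels, probabilities, threshold = 0.5) {
  counts <- confusion_counts(labels, probabilities, threshold)
  scores <- classification_scores(counts)
  auc <- if (sum(labels == 1) > 0 && sum(labels == 0) > 0) {
    auc_mw(labels, probabilities)
  } else {
    NA_real_
  }
  out <- dplyr::bind_cols(counts, scores,
                          tibble(auc = auc, threshold = threshold))
  class(out) <- c("eval_report", class(out))
  out
}
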