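#' Rank-based AUC with the midrank tie convention
#'
#' The probability that a random positive outranks a random negative,
#' ties counting one half — equivalent to trapezoidal integration of the
#' ROC curve.
#'
#' @param labels Binary 0/1 vector.
#' @param probabilities Scores of any scale (monotone in confidence).
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(labels, probabilities) {
  stopifnot(length(labels) == length(probabilities))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    bs_abort("AUC is undefined with a single class.", "degenerate_labels")
  }
  r <- rank(probabilities)  # midranks
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion-matrix and ranking metrics for binary predictions
#'
#' Hard calls are made at `threshold` for ACC, MCC, sensitivity and
#' specificity; AUC is threshold-free ([rank_auc()]).  MCC uses the
#' convention that a zero factor in its denominator yields 0.  With
#' single-class labels the AUC is returned as `NA` with a warning; the
#' other metrics follow their closed forms, with undefined ratios
#' (empty class) also `NA`.
#'
#' @param labels Binary 0/1 vector.
#' @param probabilities Scores in `[0, 1]`.
#' @param threshold Hard-call threshold (default 0.5; a score equal to the
#'   threshold is called positive).
#' @return A one-row tibble: `acc, auc, mcc, sensitivity, specificity,
#'   tp, fp, tn, fn, threshold, n`.
#' @export
compute_metrics <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities),
            all(labels %in% c(0, 1)),
            all(probabilities >= 0 & probabilities <= 1))
  call_pos <- probabilities >= threshold
  tp <- sum(call_pos & labels == 1)
  fp <- sum(call_pos & labels == 0)
  tn <- sum(!call_pos & labels == 0)
  fn <- sum(!call_pos & labels == 1)
  n <- length(labels)
  auc <- if (length(unique(labels)) < 2L) {
    warn("AUC is undefined with a single class; returning NA.")
    NA_real_
  } else {
    rank_auc(labels, probabilities)
  }
  denom_sq <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  mcc <- if (denom_sq == 0) 0 else
    (tp * tn - fp * fn) / sqrt(tp + fp) / sqrt(tp + fn) / sqrt(tn + fp) / sqrt(tn + fn)
  tibble(
    acc = (tp + tn) / n,
    auc = auc,
    mcc = mcc,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    tp = tp, fp = fp, tn = tn, fn = fn,
    threshold = threshold, n = n
  )
}
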