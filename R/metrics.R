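#' Area under the ROC curve
#'
#' Computed as the probability that a random positive outscores a random
#' negative, with ties counting one half — the rank-statistic (Mann-Whitney)
#' form, exact for any score vector and invariant to strictly monotone
#' transforms of the scores.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 (or logical) labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    abort("both classes required for AUROC", class = "icugrud_metric_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step interpolation: thresholds sweep the distinct score values from high
#' to low and the area is `sum over threshold steps of
#' (recall_i - recall_{i-1}) * precision_i` (average precision with tied
#' scores grouped).
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    abort("both classes required for AUPRC", class = "icugrud_metric_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)  # group tied scores
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}
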