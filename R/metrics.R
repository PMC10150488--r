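#' Threshold classification metrics
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' `F1 = 2*precision*recall/(precision+recall)` at a fixed probability
#' threshold.  A zero denominator (e.g. no predicted positives) yields 0
#' for that metric, with `degenerate = TRUE` flagging the case.
#'
#' @param labels Binary vector (0/1).
#' @param scores Numeric scores in \[0, 1\].
#' @param threshold Scores `>= threshold` are predicted positive.
#' @return One-row tibble with `precision`, `recall`, `f1`, `tp`, `fp`,
#'   `fn`, `tn`, `degenerate`.
#' @export
#' @examples
#' classification_metrics(c(1, 1, 1, 1, 0, 0), c(.9, .8, .7, .2, .6, .1))
classification_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  tibble(precision = precision, recall = recall, f1 = f1,
         tp = tp, fp = fp, fn = fn, tn = tn,
         degenerate = (tp + fp) == 0 || (tp + fn) == 0 ||
           (precision + recall) == 0)
}

#' Area under the ROC curve
#'
#' Computed in closed form as the Mann-Whitney concordance
#' `P(score+ > score-) + 0.5 * P(score+ = score-)` via midranks, which
#' equals the trapezoidal area under the empirical ROC curve.
#'
#' @param labels Binary vector (0/1); both classes must be present.
#' @param scores Numeric scores (any monotone scale).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("roc_auc requires both classes present")
  r <- rank(scores)                 # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation `sum(precision_k * delta_recall_k)` over the
#' distinct score thresholds in descending order (no linear interpolation
#' between PR points); ties are grouped at a single threshold.
#'
#' @param labels Binary vector (0/1); at least one positive required.
#' @param scores Numeric scores.
#' @return AUPR in \[0, 1\].
#' @export
pr_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  P <- sum(labels == 1)
  if (P == 0) abort("pr_auc requires at least one positive")
  ord <- order(-scores)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  pp <- seq_along(lab)              # predicted positives at each cut
  keep <- c(diff(sc) != 0, TRUE)    # last index of each distinct score
  recall <- tp[keep] / P
  precision <- tp[keep] / pp[keep]
  sum(diff(c(0, recall)) * precision)
}

#' Empirical ROC and PR curve points
#'
#' @param labels Binary vector (0/1).
#' @param scores Numeric scores.
#' @return Tibble with columns `curve` (`"roc"`/`"pr"`), `x` (FPR resp.
#'   recall) and `y` (TPR resp. precision), threshold-descending.
#' @export
curve_points <- function(labels, scores) {
  labels <- as.integer(labels)
  ord <- order(-scores)
  lab <- labels[ord]
  sc <- scores[ord]
  keep <- c(diff(sc) != 0, TRUE)
  tp <- cumsum(lab)[keep]
  fp <- cumsum(1 - lab)[keep]
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  bind_rows(
    tibble(curve = "roc", x = c(0, fp / max(N, 1)), y = c(0, tp / max(P, 1))),
    tibble(curve = "pr", x = tp / max(P, 1), y = tp / (tp + fp))
  )
}
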