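# Ranking metrics for imbalanced pairwise prediction.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a uniformly drawn positive outranks a uniformly
#' drawn negative, with score ties counted one half. Computed from midranks
#' (exactly the Wilcoxon/Mann-Whitney statistic).
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary 0/1 labels.
#' @return AUC in \eqn{[0,1]}.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: both classes must be present")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (step estimator)
#'
#' Non-interpolated step-wise area over descending score thresholds
#' (the average-precision form): tied scores enter a threshold together,
#' and each recall increment contributes its precision at that threshold.
#' Stated explicitly because AUPR values differ across interpolation
#' conventions.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary 0/1 labels; at least one positive required.
#' @return AUPR in \eqn{(0,1]}.
#' @export
aupr_score <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("AUPR undefined: no positive instances")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  # collapse tied scores: keep the last index of each threshold group
  last <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- tp[last]
  fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}
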