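#' Matthews correlation coefficient from confusion counts
#'
#' MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)), defined as 0
#' when any denominator factor is 0.
#'
#' @param tp,fn,tn,fp confusion counts.
#' @return MCC in [-1, 1].
#' @export
mcc_score <- function(tp, fn, tn, fp) {
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  # products can exceed integer range; use doubles
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(as.numeric(denom))
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' AUC = fraction of (positive, negative) score pairs correctly ordered, with
#' ties counted 1/2 — computed via mid-ranks.
#'
#' @param scores numeric score vector.
#' @param labels binary vector (1 = positive).
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points over all score thresholds
#'
#' @param scores numeric score vector.
#' @param labels binary vector (1 = positive).
#' @return data.frame of (fpr, tpr) = (1 - SP, SN) points, starting at (0,0)
#'   and ending at (1,1), monotone non-decreasing in both coordinates.
#' @export
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  n_pos <- sum(lab == 1)
  n_neg <- sum(lab == 0)
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)  # last point per tied threshold
  data.frame(fpr = c(0, fp[keep] / n_neg), tpr = c(0, tp[keep] / n_pos))
}

#' Evaluate classifier scores against binary labels
#'
#' Confusion counts at the given score threshold (score >= threshold calls
#' positive), sensitivity, specificity, accuracy, MCC, rank-based AUC and the
#' full ROC curve.
#'
#' @param scores numeric vector of positive-class scores.
#' @param labels binary vector (1 = positive, 0 = negative).
#' @param threshold positive-call threshold (default 0.5).
#' @return list of class \code{eval_metrics}: tp, fn, tn, fp, sn, sp, acc,
#'   mcc, auc, roc.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  call_pos <- scores >= threshold
  tp <- sum(call_pos & labels == 1)
  fn <- sum(!call_pos & labels == 1)
  tn <- sum(!call_pos & labels == 0)
  fp <- sum(call_pos & labels == 0)
  structure(list(
    tp = tp, fn = fn, tn = tn, fp = fp,
    sn = tp / (tp + fn), sp = tn / (tn + fp),
    acc = (tp + tn) / length(labels),
    mcc = mcc_score(tp, fn, tn, fp),
    auc = auc_rank(scores, labels),
    roc = roc_points(scores, labels)
  ), class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("SN %.3f  SP %.3f  ACC %.3f  AUC %.3f  MCC %.3f  ",
              x$sn, x$sp, x$acc, x$auc, x$mcc))
  cat(sprintf("(tp %d fn %d tn %d fp %d)\n", x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}
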