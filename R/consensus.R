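#' Consensus xenomiR nomination over an unlabeled pool
#'
#' Scores every pool sequence with both trained models and nominates as
#' candidate xenomiRs only the sequences called positive by both (set
#' intersection) — the conservative rule: the consensus set can never exceed
#' either single model's call set, and raising a threshold never grows any
#' call set.
#'
#' @param rf_model trained \code{rf_model} (105-feature schema).
#' @param cnn_model trained \code{cnn_model} (one-hot input).
#' @param pool \code{mirna_records} of unlabeled candidates (non-empty).
#' @param threshold shared positive-call threshold (default 0.5).
#' @param rf_threshold,cnn_threshold per-model overrides of \code{threshold}.
#' @return data.frame with one row per pool record: \code{id},
#'   \code{sequence}, \code{rf_score}, \code{cnn_score}, \code{rf_call},
#'   \code{cnn_call}, \code{consensus_call}.
#' @export
predict_consensus <- function(rf_model, cnn_model, pool, threshold = 0.5,
                              rf_threshold = threshold,
                              cnn_threshold = threshold) {
  if (nrow(pool) == 0) stop("empty unlabeled pool")
  rf_score <- predict(rf_model, feature_matrix(pool))
  cnn_score <- predict(cnn_model, one_hot_matrix(pool, L = cnn_model$config$L))
  out <- data.frame(
    id = pool$id, sequence = pool$sequence,
    rf_score = rf_score, cnn_score = cnn_score,
    rf_call = rf_score >= rf_threshold,
    cnn_call = cnn_score >= cnn_threshold,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$consensus_call <- out$rf_call & out$cnn_call
  out
}

#' Venn-style call counts for a consensus table
#' @param consensus data.frame from \code{predict_consensus}.
#' @return named integer vector: rf_only, cnn_only, both, neither.
#' @export
consensus_counts <- function(consensus) {
  c(rf_only = sum(consensus$rf_call & !consensus$cnn_call),
    cnn_only = sum(consensus$cnn_call & !consensus$rf_call),
    both = sum(consensus$consensus_call),
    neither = sum(!consensus$rf_call & !consensus$cnn_call))
}
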