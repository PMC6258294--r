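#' Random train/test split with a balanced test set
#'
#' The test set holds \code{round(test_pos_frac * P)} positives (round half
#' up) and the same number of negatives, drawn uniformly without replacement;
#' all remaining samples form the training set. With the study's class sizes
#' (166 positives, 942 negatives, 15\%) this gives a 25+25 test set and a
#' 141+917 training set.
#'
#' @param dataset \code{labeled_dataset}.
#' @param test_pos_frac fraction of positives held out (default 0.15).
#' @param seed RNG seed.
#' @return list of class \code{train_test_split} with id vectors
#'   \code{train_pos}, \code{train_neg}, \code{test_pos}, \code{test_neg}.
#' @export
split_train_test <- function(dataset, test_pos_frac = 0.15, seed = 1L) {
  if (test_pos_frac <= 0 || test_pos_frac >= 1) {
    stop("test_pos_frac must be in (0, 1)")
  }
  pos_ids <- dataset$positives$id
  neg_ids <- dataset$negatives$id
  n_test <- floor(test_pos_frac * length(pos_ids) + 0.5)
  if (n_test < 1) stop("test fraction yields an empty test set")
  if (length(neg_ids) < n_test) stop("not enough negatives for the test set")
  with_seed(seed, {
    test_pos <- sample(pos_ids, n_test)
    test_neg <- sample(neg_ids, n_test)
    structure(list(train_pos = setdiff(pos_ids, test_pos),
                   train_neg = setdiff(neg_ids, test_neg),
                   test_pos = test_pos, test_neg = test_neg,
                   seed = as.integer(seed)),
              class = "train_test_split")
  })
}

#' Oversample the positive class to a target size
#'
#' Returns a multiset of \code{n_target} ids composed of one copy of every
#' input id plus \code{n_target - P} draws with replacement, so every
#' positive sample appears at least once and the classes can be balanced.
#'
#' @param train_pos_ids character vector of positive training ids (P ids).
#' @param n_target multiset size, >= P (typically the negative training
#'   count).
#' @param seed RNG seed.
#' @return character vector of length \code{n_target}.
#' @export
oversample_positives <- function(train_pos_ids, n_target, seed = 1L) {
  p <- length(train_pos_ids)
  if (p < 1) stop("no positive ids to oversample")
  if (n_target < p) stop("n_target must be at least the number of positives")
  extra <- if (n_target > p) {
    with_seed(seed, sample(train_pos_ids, n_target - p, replace = TRUE))
  } else character(0)
  c(train_pos_ids, extra)
}

# Assemble oversampled balanced training inputs and train both models.
# features / encoded are matrices over ALL record ids (rownames).
fit_both_models <- function(train_pos_ids, train_neg_ids, features, encoded,
                            rf_cfg, cnn_cfg, oversample_seed) {
  boosted <- oversample_positives(train_pos_ids, length(train_neg_ids),
                                  seed = oversample_seed)
  train_ids <- c(boosted, train_neg_ids)
  labels <- c(rep(1L, length(boosted)), rep(0L, length(train_neg_ids)))
  list(
    rf = train_random_forest(features[train_ids, , drop = FALSE], labels,
                             rf_cfg),
    cnn = train_cnn(encoded[train_ids, , drop = FALSE], labels, cnn_cfg),
    train_ids = train_ids, labels = labels
  )
}

# Stratified fold assignment: returns a list of id vectors (validation sets).
make_folds <- function(pos_ids, neg_ids, folds, seed) {
  with_seed(seed, {
    fp <- split(sample(pos_ids), rep_len(seq_len(folds), length(pos_ids)))
    fn <- split(sample(neg_ids), rep_len(seq_len(folds), length(neg_ids)))
    lapply(seq_len(folds), function(k) c(fp[[k]], fn[[k]]))
  })
}

#' Stratified k-fold cross-validation with oversampling inside the fold
#'
#' Folds are stratified by class. Within each fold the positive class is
#' oversampled to match the fold's negative training count only after the
#' validation fold has been removed, so no validation sample is ever
#' duplicated into training (no leakage). Both the random forest and the
#' convolutional network are trained and evaluated per fold.
#'
#' @param dataset \code{labeled_dataset}.
#' @param folds number of folds (default 5).
#' @param rf_cfg,cnn_cfg model configurations.
#' @param seed RNG seed controlling fold assignment and oversampling.
#' @param threshold positive-call score threshold.
#' @return list with \code{per_fold} (per fold, \code{eval_metrics} for each
#'   model and the leakage check), and \code{mean} (per model, mean sn, sp,
#'   acc, mcc, auc across folds).
#' @export
cross_validate <- function(dataset, folds = 5L, rf_cfg = rf_config(),
                           cnn_cfg = cnn_config(), seed = 1L,
                           threshold = 0.5) {
  if (folds < 2) stop("folds must be at least 2")
  pos_ids <- dataset$positives$id
  neg_ids <- dataset$negatives$id
  if (folds > min(length(pos_ids), length(neg_ids))) {
    stop("more folds than samples in the smaller class")
  }
  all_records <- rbind(dataset$positives, dataset$negatives)
  features <- feature_matrix(all_records)
  encoded <- one_hot_matrix(all_records, L = cnn_cfg$L)
  val_sets <- make_folds(pos_ids, neg_ids, folds, seed)
  per_fold <- vector("list", folds)
  for (k in seq_len(folds)) {
    val_ids <- val_sets[[k]]
    tr_pos <- setdiff(pos_ids, val_ids)
    tr_neg <- setdiff(neg_ids, val_ids)
    fold_seed <- (seed + 1000L * k) %% .Machine$integer.max
    fit <- fit_both_models(tr_pos, tr_neg, features, encoded,
                           rf_cfg_with_seed(rf_cfg, fold_seed),
                           cnn_cfg_with_seed(cnn_cfg, fold_seed),
                           oversample_seed = fold_seed)
    stopifnot(!any(val_ids %in% fit$train_ids))  # leakage guard
    val_labels <- as.integer(val_ids %in% pos_ids)
    rf_scores <- predict(fit$rf, features[val_ids, , drop = FALSE])
    cnn_scores <- predict(fit$cnn, encoded[val_ids, , drop = FALSE])
    per_fold[[k]] <- list(
      val_ids = val_ids,
      rf = evaluate_scores(rf_scores, val_labels, threshold),
      cnn = evaluate_scores(cnn_scores, val_labels, threshold)
    )
  }
  mean_of <- function(model) {
    vapply(c("sn", "sp", "acc", "mcc", "auc"), function(met) {
      mean(vapply(per_fold, function(f) f[[model]][[met]], numeric(1)))
    }, numeric(1))
  }
  list(per_fold = per_fold,
       mean = list(rf = mean_of("rf"), cnn = mean_of("cnn")))
}

rf_cfg_with_seed <- function(cfg, seed) {
  cfg$seed <- as.integer(seed); cfg
}

cnn_cfg_with_seed <- function(cfg, seed) {
  cfg$seed <- as.integer(seed); cfg
}
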