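write_csv_out <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

run_manifest <- function(out_dir, files, seed) {
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  info <- c(sprintf("seed\t%s", seed),
            sprintf("r_version\t%s", R.version.string),
            sprintf("package_version\t%s",
                    as.character(utils::packageVersion("xenomir"))),
            sprintf("%s\t%s", manifest$file, manifest$md5))
  writeLines(info, file.path(out_dir, "MANIFEST.tsv"))
  invisible(manifest)
}

#' Group-statistics stage: feature screen, composition, LDA
#'
#' Runs the descriptive-statistics arm of the pipeline on a labeled dataset:
#' the 105-feature Wilcoxon/FDR screen, per-group positional composition
#' profiles, LD1 scores with the within-group compactness test, and (if a
#' family map is supplied) the per-family mapping summary. Optionally writes
#' every table plus a run manifest to \code{out_dir}.
#'
#' @param dataset \code{labeled_dataset}.
#' @param alpha FDR significance threshold (default 0.01).
#' @param family_map optional named vector of family sizes.
#' @param out_dir optional output directory (created if missing).
#' @param seed recorded in the manifest (the stage itself is deterministic).
#' @return list with \code{features_pos}, \code{features_neg},
#'   \code{comparison}, \code{composition_pos}, \code{composition_neg},
#'   \code{lda}, \code{compactness}, and optionally \code{families}.
#' @export
run_statistics <- function(dataset, alpha = 0.01, family_map = NULL,
                           out_dir = NULL, seed = 1L) {
  if (nrow(dataset$positives) == 0 || nrow(dataset$negatives) == 0) {
    stop("both classes must be non-empty")
  }
  fpos <- feature_matrix(dataset$positives)
  fneg <- feature_matrix(dataset$negatives)
  comparison <- compare_feature_groups(fpos, fneg, alpha = alpha)
  comp_pos <- position_composition(dataset$positives)
  comp_neg <- position_composition(dataset$negatives)
  lda <- lda_ld1(fpos, fneg)
  compact <- ld1_compactness_test(lda)
  out <- list(features_pos = fpos, features_neg = fneg,
              comparison = comparison,
              composition_pos = comp_pos, composition_neg = comp_neg,
              lda = lda, compactness = compact)
  if (!is.null(family_map)) {
    out$families <- family_summary(rbind(dataset$positives,
                                         dataset$negatives), family_map)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      write_csv_out(feature_table(rbind(dataset$positives,
                                        dataset$negatives)),
                    out_dir, "feature_matrix.csv"),
      write_csv_out(comparison, out_dir, "feature_comparison.csv"),
      write_csv_out(data.frame(position = seq_len(POSITION_WIDTH),
                               comp_pos$percent,
                               denominator = comp_pos$denominator),
                    out_dir, "composition_positives.csv"),
      write_csv_out(data.frame(position = seq_len(POSITION_WIDTH),
                               comp_neg$percent,
                               denominator = comp_neg$denominator),
                    out_dir, "composition_negatives.csv"),
      write_csv_out(data.frame(
        id = c(dataset$positives$id, dataset$negatives$id),
        label = c(rep("positive", nrow(dataset$positives)),
                  rep("negative", nrow(dataset$negatives))),
        ld1 = c(lda$ld1_pos, lda$ld1_neg)),
        out_dir, "ld1_scores.csv")
    )
    if (!is.null(out$families)) {
      files <- c(files, write_csv_out(out$families, out_dir,
                                      "family_summary.csv"))
    }
    run_manifest(out_dir, files, seed)
  }
  out
}

#' Full modelling stage: split, train, evaluate, cross-validate, predict
#'
#' The modelling arm of the pipeline: hold out a balanced test set, balance
#' the training classes by oversampling positives, train the random forest
#' and the convolutional network, evaluate both on the held-out test set,
#' run stratified 5-fold cross-validation (oversampling inside each fold),
#' extract random-forest feature importance, and, if a pool is supplied,
#' nominate consensus candidates. One global seed determines the split,
#' oversampling, fold assignment and both model fits.
#'
#' @param dataset \code{labeled_dataset}.
#' @param pool optional \code{mirna_records} of unlabeled candidates.
#' @param test_pos_frac held-out positive fraction (default 0.15).
#' @param folds cross-validation folds (default 5).
#' @param rf_cfg,cnn_cfg model configurations (seeds are re-derived from
#'   \code{seed}).
#' @param threshold positive-call threshold (default 0.5).
#' @param seed global RNG seed.
#' @param run_cv set FALSE to skip cross-validation.
#' @param out_dir optional output directory.
#' @return list with \code{split}, \code{models}, \code{test} (per-model
#'   \code{eval_metrics}), \code{cv}, \code{importance}, and optionally
#'   \code{consensus}.
#' @export
run_full <- function(dataset, pool = NULL, test_pos_frac = 0.15, folds = 5L,
                     rf_cfg = rf_config(), cnn_cfg = cnn_config(),
                     threshold = 0.5, seed = 1L, run_cv = TRUE,
                     out_dir = NULL) {
  seed <- as.integer(seed)
  split <- split_train_test(dataset, test_pos_frac, seed = seed)
  all_records <- rbind(dataset$positives, dataset$negatives)
  features <- feature_matrix(all_records)
  encoded <- one_hot_matrix(all_records, L = cnn_cfg$L)
  fit <- fit_both_models(split$train_pos, split$train_neg, features, encoded,
                         rf_cfg_with_seed(rf_cfg, seed + 1L),
                         cnn_cfg_with_seed(cnn_cfg, seed + 2L),
                         oversample_seed = seed + 3L)
  test_ids <- c(split$test_pos, split$test_neg)
  test_labels <- c(rep(1L, length(split$test_pos)),
                   rep(0L, length(split$test_neg)))
  rf_scores <- predict(fit$rf, features[test_ids, , drop = FALSE])
  cnn_scores <- predict(fit$cnn, encoded[test_ids, , drop = FALSE])
  test <- list(rf = evaluate_scores(rf_scores, test_labels, threshold),
               cnn = evaluate_scores(cnn_scores, test_labels, threshold))
  cv <- if (run_cv) {
    cross_validate(dataset, folds = folds, rf_cfg = rf_cfg,
                   cnn_cfg = cnn_cfg, seed = seed + 4L,
                   threshold = threshold)
  }
  importance <- rf_importance(fit$rf)
  out <- list(split = split, models = fit[c("rf", "cnn")], test = test,
              cv = cv, importance = importance)
  if (!is.null(pool)) {
    out$consensus <- predict_consensus(fit$rf, fit$cnn, pool,
                                       threshold = threshold)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    metrics_df <- do.call(rbind, lapply(
      list(c("RF", "test"), c("CNN", "test"),
           if (run_cv) c("RF", "cv_mean"), if (run_cv) c("CNN", "cv_mean")),
      function(spec) {
        if (is.null(spec)) return(NULL)
        model <- spec[1]; set <- spec[2]
        vals <- if (set == "test") {
          m <- test[[tolower(model)]]
          c(m$sn, m$sp, m$acc, m$auc, m$mcc)
        } else {
          cv$mean[[tolower(model)]][c("sn", "sp", "acc", "auc", "mcc")]
        }
        data.frame(model = model, set = set, sn = vals[1], sp = vals[2],
                   acc = vals[3], auc = vals[4], mcc = vals[5])
      }))
    files <- c(
      write_csv_out(metrics_df, out_dir, "metrics.csv"),
      write_csv_out(importance, out_dir, "rf_importance.csv"),
      write_csv_out(data.frame(set = c("train_pos", "train_neg",
                                       "test_pos", "test_neg"),
                               n = c(length(split$train_pos),
                                     length(split$train_neg),
                                     length(split$test_pos),
                                     length(split$test_neg))),
                    out_dir, "split_sizes.csv"),
      write_csv_out(data.frame(model = rep(c("RF", "CNN"),
                                           c(nrow(test$rf$roc),
                                             nrow(test$cnn$roc))),
                               rbind(test$rf$roc, test$cnn$roc)),
                    out_dir, "roc_test.csv")
    )
    if (!is.null(out$consensus)) {
      files <- c(files,
                 write_csv_out(out$consensus, out_dir, "consensus.csv"))
    }
    run_manifest(out_dir, files, seed)
  }
  out
}
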