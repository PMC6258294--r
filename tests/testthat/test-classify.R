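make_dataset <- function(n_pos, n_neg, seed = 1) {
  set.seed(seed)
  pos <- make_records(vapply(seq_len(n_pos), function(i) random_rna(20),
                             character(1)),
                      ids = sprintf("p%04d", seq_len(n_pos)),
                      label = "positive")
  neg <- make_records(vapply(seq_len(n_neg), function(i) random_rna(21),
                             character(1)),
                      ids = sprintf("n%04d", seq_len(n_neg)),
                      label = "negative")
  labeled_dataset(pos, neg)
}

test_that("train/test split reproduces the study's class arithmetic", {
  ds <- make_dataset(166, 942)
  sp <- split_train_test(ds, 0.15, seed = 7)
  expect_length(sp$test_pos, 25)
  expect_length(sp$test_neg, 25)
  expect_length(sp$train_pos, 141)
  expect_length(sp$train_neg, 917)
  expect_length(intersect(sp$train_pos, sp$test_pos), 0)
  expect_setequal(c(sp$train_pos, sp$test_pos), ds$positives$id)
  expect_setequal(c(sp$train_neg, sp$test_neg), ds$negatives$id)
  # same seed, same split; different seed, (almost surely) different
  sp2 <- split_train_test(ds, 0.15, seed = 7)
  expect_identical(sp[1:4], sp2[1:4])

  small <- make_dataset(20, 50)
  sp3 <- split_train_test(small, 0.15, seed = 1)
  expect_length(sp3$test_pos, 3)  # round(0.15 * 20) = 3
  expect_error(split_train_test(ds, 1.5), "in \\(0, 1\\)")
})

test_that("oversampling yields a covering multiset of the target size", {
  ids <- c("a", "b", "c")
  os <- oversample_positives(ids, 5, seed = 3)
  expect_length(os, 5)
  expect_setequal(unique(os), ids)
  # forced identity when target equals the class size
  expect_setequal(oversample_positives(ids, 3), ids)
  expect_length(oversample_positives(ids, 3), 3)
  expect_error(oversample_positives(ids, 2), "at least")

  big <- oversample_positives(sprintf("p%03d", 1:141), 917, seed = 1)
  expect_length(big, 917)
  expect_length(unique(big), 141)
})

test_that("random forest training validates inputs and is reproducible", {
  ds <- make_dataset(30, 60)
  feats <- feature_matrix(rbind(ds$positives, ds$negatives))
  labels <- c(rep(1, 30), rep(0, 60))
  expect_error(train_random_forest(feats, rep(1, 90)), "both classes")
  expect_error(train_random_forest(feats[, 1:10], labels), "schema")
  cfg <- rf_config(n_trees = 101, seed = 5)
  m1 <- train_random_forest(feats, labels, cfg)
  m2 <- train_random_forest(feats, labels, cfg)
  expect_identical(predict(m1, feats), predict(m2, feats))
  expect_true(all(predict(m1, feats) >= 0 & predict(m1, feats) <= 1))
})

test_that("rf importance flags ceil(10%) of features per criterion", {
  ds <- make_dataset(25, 50)
  feats <- feature_matrix(rbind(ds$positives, ds$negatives))
  m <- train_random_forest(feats, c(rep(1, 25), rep(0, 50)),
                           rf_config(n_trees = 101, seed = 2))
  imp <- rf_importance(m)
  expect_equal(nrow(imp), 105)
  expect_equal(sum(imp$top_gini), 11)
  expect_equal(sum(imp$top_accuracy), 11)
  expect_true(all(diff(imp$mean_decrease_gini) <= 0))
})

test_that("a constant feature gets (near-)zero importance", {
  ds <- make_dataset(25, 50)
  feats <- feature_matrix(rbind(ds$positives, ds$negatives))
  # CAG frequency is whatever it is; overwrite one column to a constant
  feats[, "GGG"] <- 0.5
  m <- train_random_forest(feats, c(rep(1, 25), rep(0, 50)),
                           rf_config(n_trees = 101, seed = 2))
  imp <- rf_importance(m)
  row <- imp[imp$feature == "GGG", ]
  expect_equal(row$mean_decrease_gini, 0)
  expect_equal(row$mean_decrease_accuracy, 0)
})

test_that("the CNN learns a linearly separable toy problem", {
  set.seed(13)
  pos_seqs <- vapply(1:40, function(i) paste0("CCC", random_rna(17)),
                     character(1))
  neg_seqs <- vapply(1:40, function(i) paste0("UUU", random_rna(17)),
                     character(1))
  recs <- make_records(c(pos_seqs, neg_seqs))
  enc <- one_hot_matrix(recs)
  labels <- rep(c(1, 0), each = 40)
  model <- train_cnn(enc, labels, cnn_config(seed = 17))
  acc <- mean((predict(model, enc) >= 0.5) == labels)
  expect_gte(acc, 0.95)
})

test_that("CNN training is deterministic and validates input width", {
  set.seed(19)
  recs <- make_records(vapply(1:30, function(i) random_rna(20), character(1)))
  enc <- one_hot_matrix(recs)
  labels <- rep(c(1, 0), 15)
  m1 <- train_cnn(enc, labels, tiny_cnn(seed = 23))
  m2 <- train_cnn(enc, labels, tiny_cnn(seed = 23))
  expect_identical(predict(m1, enc), predict(m2, enc))
  p <- predict(m1, enc)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(train_cnn(enc[, 1:70], labels, tiny_cnn()), "width")
  expect_error(predict(m1, enc[, 1:70]), "width")
  expect_error(train_cnn(enc, rep(1, 30), tiny_cnn()), "both classes")
})

test_that("CNN backpropagation matches finite-difference gradients", {
  set.seed(29)
  cfg <- cnn_config(conv_channels = c(3L, 2L), conv_kernels = c(4L, 3L),
                    dense_units = c(5L, 4L), dropout_rate = 0, l2_lambda = 0.01,
                    epochs = 1L, batch_size = 4L, L = 12L, seed = 31)
  n <- 6
  X <- t(vapply(seq_len(n), function(i) one_hot_encode(random_rna(12), L = 12),
                integer(48)))
  labels <- rep(c(1, 0), 3)
  Y <- cbind(1 - labels, labels)
  set.seed(31)
  p <- xenomir:::cnn_init_params(cfg)
  masks <- list(m1 = 1, m2 = 1)
  loss_at <- function(params) {
    pr <- xenomir:::cnn_forward(X, params, cfg, masks)$probs
    -sum(Y * log(pr)) / n +
      cfg$l2_lambda / 2 * (sum(params$Wd1^2) + sum(params$Wd2^2))
  }
  cache <- xenomir:::cnn_forward(X, p, cfg, masks, keep_cache = TRUE)
  grads <- xenomir:::cnn_gradients(cache, Y, p, cfg, masks)
  eps <- 1e-6
  for (nm in names(p)) {
    # probe a handful of coordinates of each parameter block
    idx <- seq_len(min(4, length(p[[nm]])))
    for (j in idx) {
      up <- p; up[[nm]][j] <- up[[nm]][j] + eps
      dn <- p; dn[[nm]][j] <- dn[[nm]][j] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(unname(grads[[nm]][j]), num, tolerance = 1e-4,
                   label = paste("grad", nm, j))
    }
  }
})

test_that("cross-validation partitions cleanly and never leaks", {
  ds <- make_dataset(24, 48, seed = 3)
  res <- cross_validate(ds, folds = 4, rf_cfg = rf_config(n_trees = 51),
                        cnn_cfg = tiny_cnn(epochs = 2), seed = 5)
  val_ids <- unlist(lapply(res$per_fold, `[[`, "val_ids"))
  expect_setequal(val_ids, c(ds$positives$id, ds$negatives$id))
  expect_length(val_ids, 72)  # each sample in exactly one validation fold
  for (f in res$per_fold) {
    expect_s3_class(f$rf, "eval_metrics")
    expect_s3_class(f$cnn, "eval_metrics")
  }
  expect_named(res$mean$rf, c("sn", "sp", "acc", "mcc", "auc"))
  expect_error(cross_validate(ds, folds = 30), "folds")
})

test_that("oversampling inside a fold never duplicates validation samples", {
  ds <- make_dataset(20, 40, seed = 9)
  feats <- feature_matrix(rbind(ds$positives, ds$negatives))
  enc <- one_hot_matrix(rbind(ds$positives, ds$negatives))
  val_sets <- xenomir:::make_folds(ds$positives$id, ds$negatives$id, 5, 11)
  for (k in seq_along(val_sets)) {
    tr_pos <- setdiff(ds$positives$id, val_sets[[k]])
    tr_neg <- setdiff(ds$negatives$id, val_sets[[k]])
    boosted <- oversample_positives(tr_pos, length(tr_neg), seed = k)
    expect_length(intersect(boosted, val_sets[[k]]), 0)
    expect_length(boosted, length(tr_neg))  # exactly balanced
    expect_setequal(unique(boosted), tr_pos)
  }
})

test_that("random hyperparameter search is seeded and picks the best trial", {
  set.seed(37)
  recs <- make_records(vapply(1:60, function(i) random_rna(20), character(1)))
  enc <- one_hot_matrix(recs)
  labels <- rep(c(1, 0), 30)
  tuned <- tune_cnn_random(enc, labels, n_trials = 2, epochs = 2, seed = 41)
  expect_equal(nrow(tuned$trials), 2)
  expect_s3_class(tuned$best, "cnn_config")
  best_row <- tuned$trials[which.max(tuned$trials$val_auc), ]
  expect_equal(tuned$best$dropout_rate, best_row$dropout)
  expect_equal(tuned$best$l2_lambda, best_row$l2)
  tuned2 <- tune_cnn_random(enc, labels, n_trials = 2, epochs = 2, seed = 41)
  expect_identical(tuned$trials, tuned2$trials)
  expect_error(tune_cnn_random(enc[1:6, ], labels[1:6]), "too few")
})
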