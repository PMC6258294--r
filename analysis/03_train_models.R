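#!/usr/bin/env Rscript
# Stage 3 — train and evaluate the two classifiers.
#
# Reads the labeled FASTA files from 01_simulate.R, holds out a 25+25 test
# set (15% of positives, equal negatives), oversamples training positives to
# balance the classes, trains the 501-tree random forest on the 105 features
# and the 1-D CNN on the one-hot encoded first 18 nt, evaluates both on the
# held-out test set and by stratified 5-fold CV (oversampling inside each
# fold), and writes metrics, ROC points and RF importance under
# results/models/. The fitted models are saved for stage 4.

suppressPackageStartupMessages(library(xenomir))

data_dir <- "results/data"
out <- "results/models"
stopifnot(file.exists(file.path(data_dir, "positives.fa")))
seed <- 1L

ds <- labeled_dataset(
  read_mirna_fasta(file.path(data_dir, "positives.fa"), label = "positive"),
  read_mirna_fasta(file.path(data_dir, "negatives.fa"), label = "negative")
)

res <- run_full(ds, seed = seed, out_dir = out)

cat(sprintf("split: train %d+%d, test %d+%d\n",
            length(res$split$train_pos), length(res$split$train_neg),
            length(res$split$test_pos), length(res$split$test_neg)))
cat("held-out test performance:\n")
cat("  RF : "); print(res$test$rf)
cat("  CNN: "); print(res$test$cnn)
cat("5-fold CV means (sn sp acc mcc auc):\n")
cat("  RF :", sprintf("%.3f", res$cv$mean$rf), "\n")
cat("  CNN:", sprintf("%.3f", res$cv$mean$cnn), "\n")
cat("top Gini-importance features:",
    paste(head(res$importance$feature, 5), collapse = ", "), "\n")

saveRDS(res$models, file.path(out, "models.rds"))
cat(sprintf("metrics and fitted models written to %s\n", out))
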