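#!/usr/bin/env Rscript
# Stage 4 — nominate candidate xenomiRs from the unlabeled pool.
#
# Loads the models fitted in 03_train_models.R, scores the 3695-sequence
# unlabeled pool with both, and keeps the conservative consensus: only
# sequences called positive by the random forest AND the CNN. Because the
# pool is synthetic we can also score precision against the hidden truth —
# something the real study could not do.

suppressPackageStartupMessages(library(xenomir))

data_dir <- "results/data"
out <- "results/consensus"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
models <- readRDS("results/models/models.rds")

pool <- read_mirna_fasta(file.path(data_dir, "pool.fa"), label = "unlabeled")
truth <- read.delim(file.path(data_dir, "pool_truth.tsv"))

cons <- predict_consensus(models$rf, models$cnn, pool)
write.csv(cons, file.path(out, "consensus.csv"), row.names = FALSE)

counts <- consensus_counts(cons)
cat(sprintf("pool %d: RF calls %d, CNN calls %d, consensus %d\n",
            nrow(cons), sum(cons$rf_call), sum(cons$cnn_call),
            counts[["both"]]))

stopifnot(identical(cons$id, truth$id))
prec <- function(call) if (sum(call) == 0) NA else mean(truth$truth[call] == 1)
cat(sprintf("precision vs hidden truth: RF %.3f, CNN %.3f, consensus %.3f\n",
            prec(cons$rf_call), prec(cons$cnn_call),
            prec(cons$consensus_call)))
cat(sprintf("consensus table written to %s\n", out))
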