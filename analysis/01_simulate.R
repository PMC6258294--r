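#!/usr/bin/env Rscript
# Stage 1 — simulate the study's sequence sets.
#
# Generates a labeled xenomiR/non-xenomiR dataset (166/942) and a
# 3695-sequence unlabeled pool from the planted-difference generator
# (positives: more C, less U, CAG enriched, ~1 nt shorter), and writes them
# as FASTA + TSV under results/data/. The pool's hidden truth labels are
# written separately; downstream stages never feed them to a model.

suppressPackageStartupMessages(library(xenomir))

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- table1_like_config(seed = seed)
gen <- generate_dataset(cfg)

write_mirna_fasta(gen$dataset$positives, file.path(out, "positives.fa"))
write_mirna_fasta(gen$dataset$negatives, file.path(out, "negatives.fa"))
write_mirna_fasta(gen$pool, file.path(out, "pool.fa"))
write.table(gen$pool[, c("id", "truth")], file.path(out, "pool_truth.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

cat(sprintf("wrote %d positives, %d negatives, %d pool sequences to %s\n",
            nrow(gen$dataset$positives), nrow(gen$dataset$negatives),
            nrow(gen$pool), out))
cat(sprintf("pool contains %d true xenomiR-like sequences (hidden truth)\n",
            sum(gen$pool$truth)))
cat(sprintf("mean length pos %.1f nt vs neg %.1f nt\n",
            mean(nchar(gen$dataset$positives$sequence)),
            mean(nchar(gen$dataset$negatives$sequence))))
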