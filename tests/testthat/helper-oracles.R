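# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / enumeration, never through the package's own
# code paths.

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(n1+n2, n1) group assignments. Distinct values only.
enumerate_wilcox_p <- function(x, y) {
  stopifnot(!anyDuplicated(c(x, y)))
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Benjamini-Hochberg by the step-up formula, written out directly.
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  stepped <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(stepped)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# AUC by counting every (positive, negative) score pair.
pair_count_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  total <- 0
  for (a in sp) for (b in sn) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(sp) * length(sn))
}

# k-mer counting by explicit window loop.
count_kmers_loop <- function(seq, k) {
  kmers <- character(0)
  for (i in seq_len(nchar(seq) - k + 1)) {
    kmers <- c(kmers, substr(seq, i, i + k - 1))
  }
  table(kmers)
}

# Random valid RNA sequence.
random_rna <- function(len) {
  paste0(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Small record set builder.
make_records <- function(seqs, ids = sprintf("m%03d", seq_along(seqs)),
                         label = "unlabeled", abundance = NA_real_) {
  mirna_records(ids, seqs, label = label, abundance = abundance)
}

# Quick CNN config for tests that only need mechanics, not accuracy.
tiny_cnn <- function(seed = 1L, epochs = 3L) {
  cnn_config(conv_channels = c(4L, 4L), conv_kernels = c(5L, 3L),
             dense_units = c(8L, 4L), dropout_rate = 0.2, epochs = epochs,
             batch_size = 16L, seed = seed)
}

# Reduced synthetic config with the planted effect, for runtime-bounded
# stochastic properties.
small_planted_config <- function(seed, n_pos = 120L, n_neg = 400L,
                                 n_unlabeled = 400L) {
  table1_like_config(seed = seed, n_pos = n_pos, n_neg = n_neg,
                     n_unlabeled = n_unlabeled)
}
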