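# position_composition works on arbitrary-length strings; use the records
# constructor bypass via short synthetic sequences padded to valid length.
test_that("positional composition percentages are counted per covered position", {
  recs <- make_records(c("ACGUACGUACGUACGUACG", "ACGUACGUACGUACGUACG",
                         "AUGUACGUACGUACGUACGUA"))
  comp <- position_composition(recs)
  expect_equal(unname(comp$percent[1, "A"]), 100)
  expect_equal(unname(comp$percent[2, "C"]), 100 * 2 / 3)
  expect_equal(unname(comp$percent[2, "U"]), 100 * 1 / 3)
  # positions beyond the longest sequence are undefined with zero denominator
  expect_equal(comp$denominator[20], 1)
  expect_equal(comp$denominator[22], 0)
  expect_true(all(is.na(comp$percent[22, ])))
  # covered rows sum to 100
  covered <- comp$denominator > 0
  expect_equal(unname(rowSums(comp$percent[covered, , drop = FALSE])),
               rep(100, sum(covered)), tolerance = 1e-9)
  expect_error(position_composition(recs[0, ]), "empty")
})

test_that("feature screen on identical groups finds nothing", {
  set.seed(21)
  recs <- make_records(vapply(1:12, function(i) random_rna(20), character(1)))
  mat <- feature_matrix(recs)
  cmp <- compare_feature_groups(mat, mat)
  expect_equal(nrow(cmp), 105)
  expect_true(all(cmp$p_value > 0.9))
  expect_false(any(cmp$significant))
  expect_identical(cmp$feature, sort(cmp$feature))
})

test_that("a single fully separated feature is the only significant one", {
  set.seed(31)
  base <- make_records(vapply(1:40, function(i) random_rna(20), character(1)))
  mat <- feature_matrix(base)
  pos <- mat[1:20, ]
  neg <- mat[1:20, ]  # identical except the planted column
  # plant complete separation in "length" with distinct values (exact path)
  pos[, "length"] <- seq(1.001, 2, length.out = 20)
  neg[, "length"] <- seq(0.001, 1, length.out = 20)
  cmp <- compare_feature_groups(pos, neg)
  planted <- cmp[cmp$feature == "length", ]
  # exact extreme two-sided tail at 20 vs 20
  expect_equal(planted$p_value, min(1, 2 / choose(40, 20)))
  expect_true(planted$significant)
  expect_equal(sum(cmp$significant), 1)
  expect_equal(planted$mean_pos, mean(pos[, "length"]))
  expect_equal(planted$mean_neg, mean(neg[, "length"]))
})

test_that("screen p-values match exact rank-sum enumeration for small groups", {
  set.seed(41)
  for (i in 1:8) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    vals <- sample(seq(0.01, 0.99, by = 0.01), n1 + n2)  # distinct, tie-free
    x <- matrix(vals[seq_len(n1)], ncol = 1,
                dimnames = list(NULL, "f"))
    y <- matrix(vals[n1 + seq_len(n2)], ncol = 1,
                dimnames = list(NULL, "f"))
    cmp <- compare_feature_groups(x, y)
    expect_equal(cmp$p_value, enumerate_wilcox_p(drop(x), drop(y)),
                 tolerance = 1e-12)
  }
})

test_that("FDR column reproduces step-up Benjamini-Hochberg by hand", {
  set.seed(51)
  recs_a <- make_records(vapply(1:15, function(i) random_rna(19), character(1)))
  recs_b <- make_records(vapply(1:15, function(i) random_rna(21), character(1)))
  cmp <- compare_feature_groups(feature_matrix(recs_a), feature_matrix(recs_b))
  expect_equal(cmp$fdr, bh_by_hand(cmp$p_value))
  expect_true(all(cmp$fdr >= cmp$p_value))
  # monotone in the p-value ordering
  o <- order(cmp$p_value)
  expect_true(all(diff(cmp$fdr[o]) >= -1e-15))
  expect_equal(cmp$significant, cmp$fdr < 0.01)
})

test_that("LD1 separates planted clouds and honours the sign convention", {
  set.seed(61)
  n <- 30
  recs <- make_records(vapply(1:60, function(i) random_rna(20), character(1)))
  base <- feature_matrix(recs)
  delta <- rep(0, 105)
  delta[base[1, ] > 0] <- 0.2
  pos <- base[1:n, ] + matrix(delta, n, 105, byrow = TRUE)
  neg <- base[n + 1:n, ] - matrix(delta, n, 105, byrow = TRUE)
  res <- lda_ld1(pos, neg)
  expect_length(res$ld1_pos, n)
  expect_length(res$ld1_neg, n)
  expect_gt(min(res$ld1_pos), max(res$ld1_neg))  # zero overlap
  # label swap negates every score
  swapped <- lda_ld1(neg, pos)
  expect_equal(swapped$ld1_pos, -res$ld1_neg, tolerance = 1e-8)
  expect_equal(swapped$ld1_neg, -res$ld1_pos, tolerance = 1e-8)
  # identical groups: no systematic separation
  same <- lda_ld1(base[1:n, ], base[1:n, ])
  expect_equal(mean(same$ld1_pos), mean(same$ld1_neg), tolerance = 1e-8)
})

test_that("LD1 direction agrees with Fisher LDA on full-rank data", {
  skip_if_not_installed("MASS")
  set.seed(71)
  p <- 5
  pos <- matrix(rnorm(40 * p, mean = 0.5), 40, p,
                dimnames = list(NULL, paste0("f", 1:p)))
  neg <- matrix(rnorm(40 * p), 40, p,
                dimnames = list(NULL, paste0("f", 1:p)))
  res <- lda_ld1(pos, neg)
  fit <- MASS::lda(rbind(pos, neg), grouping = rep(c("p", "n"), each = 40))
  ref <- drop(rbind(pos, neg) %*% fit$scaling)
  ours <- c(res$ld1_pos, res$ld1_neg)
  expect_gt(abs(cor(ours, ref)), 0.999)
})

test_that("compactness test matches the closed-form 3-vs-3 example", {
  res <- structure(list(ld1_pos = c(0, 0, 0), ld1_neg = c(0, 10, 20)),
                   class = "lda_result")
  out <- ld1_compactness_test(res)
  expect_equal(sort(out$distances_pos), c(0, 0, 0))
  expect_equal(sort(out$distances_neg), c(10, 10, 20))
  # Welch t on {0,0,0} vs {10,10,20}: t = -40/3 / sqrt((100/3)/3) = -4, df = 2
  expect_equal(out$t, -4)
  expect_equal(out$p_value, 2 * stats::pt(-4, 2))
  expect_lt(out$p_value, 0.1)

  # identical score multisets: degenerate, t = 0, p = 1
  same <- structure(list(ld1_pos = c(1, 2), ld1_neg = c(1, 2)),
                    class = "lda_result")
  out2 <- ld1_compactness_test(same)
  expect_equal(out2$t, 0)
  expect_equal(out2$p_value, 1)
  expect_error(ld1_compactness_test(
    structure(list(ld1_pos = 1, ld1_neg = c(1, 2)), class = "lda_result")),
    "at least 2")
})

test_that("pairwise distance counts are n(n-1)/2 per group", {
  set.seed(81)
  res <- structure(list(ld1_pos = rnorm(9), ld1_neg = rnorm(14)),
                   class = "lda_result")
  out <- ld1_compactness_test(res)
  expect_length(out$distances_pos, 9 * 8 / 2)
  expect_length(out$distances_neg, 14 * 13 / 2)
})

test_that("family summaries report mapped counts and fractions", {
  recs <- make_records(vapply(1:11, function(i) random_rna(20), character(1)))
  recs$family <- c(rep("mir168", 7), rep("mir156", 3), NA)
  fmap <- c(mir168 = 17, mir156 = 3)
  fs <- family_summary(recs, fmap)
  expect_equal(fs$n_mapped, c(7, 3))
  expect_equal(round(100 * fs$fraction[fs$family == "mir168"], 1), 41.2)
  expect_equal(fs$fraction[fs$family == "mir156"], 1)
  expect_error(family_summary(recs, c(mir168 = 17)), "missing")
  empty <- family_summary(recs[0, ], fmap)
  expect_equal(nrow(empty), 0)
})
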