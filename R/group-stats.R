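#' Per-position nucleotide composition of a sequence group
#'
#' For each of the first 24 positions, the percentage of A/C/G/U among the
#' sequences long enough to cover that position. Positions not covered by any
#' sequence have denominator 0 and NA percentages.
#'
#' @param records \code{mirna_records} (non-empty).
#' @return list with \code{percent} (24 x 4 matrix of percentages) and
#'   \code{denominator} (per-position sequence counts).
#' @export
position_composition <- function(records) {
  if (nrow(records) == 0) stop("empty group")
  chars <- strsplit(records$sequence, "")
  percent <- matrix(NA_real_, POSITION_WIDTH, 4,
                    dimnames = list(sprintf("pos%02d", seq_len(POSITION_WIDTH)),
                                    RNA_BASES))
  denom <- integer(POSITION_WIDTH)
  for (i in seq_len(POSITION_WIDTH)) {
    at <- vapply(chars, function(ch) if (length(ch) >= i) ch[i] else NA_character_,
                 character(1))
    at <- at[!is.na(at)]
    denom[i] <- length(at)
    if (denom[i] > 0) {
      percent[i, ] <- 100 * as.numeric(table(factor(at, levels = RNA_BASES))) /
        denom[i]
    }
  }
  list(percent = percent, denominator = denom)
}

#' Per-feature two-group comparison with FDR control
#'
#' For each of the 105 model features, a two-sided Wilcoxon rank-sum test
#' between the positive and negative groups, Benjamini-Hochberg FDR across
#' all features, group means, and a significance flag at \code{fdr < alpha}.
#' The exact null distribution is used when both groups have at most 25
#' samples and the feature has no ties; otherwise the normal approximation
#' with tie and continuity correction.
#'
#' @param pos_features,neg_features numeric matrices over the same model
#'   feature schema (columns), one row per miRNA.
#' @param alpha FDR significance threshold (default 0.01).
#' @return data.frame sorted by feature name with columns \code{feature},
#'   \code{p_value}, \code{fdr}, \code{mean_pos}, \code{mean_neg},
#'   \code{significant}.
#' @export
compare_feature_groups <- function(pos_features, neg_features, alpha = 0.01) {
  if (!identical(colnames(pos_features), colnames(neg_features))) {
    stop("feature schema mismatch between groups")
  }
  if (nrow(pos_features) < 2 || nrow(neg_features) < 2) {
    stop("each group needs at least 2 samples")
  }
  want_exact <- nrow(pos_features) <= 25 && nrow(neg_features) <= 25
  p <- vapply(colnames(pos_features), function(f) {
    x <- pos_features[, f]
    y <- neg_features[, f]
    if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) return(1.0)
    suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = want_exact, correct = TRUE)$p.value
    )
  }, numeric(1))
  out <- data.frame(
    feature = colnames(pos_features),
    p_value = p,
    fdr = stats::p.adjust(p, method = "BH"),
    mean_pos = colMeans(pos_features),
    mean_neg = colMeans(neg_features),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$significant <- out$fdr < alpha
  out[order(out$feature), , drop = FALSE]
}

#' Two-class Fisher linear discriminant scores (LD1)
#'
#' Features are standardised to zero mean and unit variance, the pooled
#' within-class scatter is ridge-regularised (the k-mer frequency families
#' each sum to 1, so the raw scatter is rank-deficient), and every sample is
#' projected onto the Fisher direction. Orientation is fixed so the positive
#' group has the larger mean score.
#'
#' @param pos_features,neg_features numeric matrices over the same schema.
#' @param ridge relative ridge weight; the added term is
#'   \code{ridge * trace(Sw)/p} on the scatter diagonal.
#' @return list of class \code{lda_result} with \code{ld1_pos},
#'   \code{ld1_neg} (score vectors) and \code{direction} (named weights).
#' @export
lda_ld1 <- function(pos_features, neg_features, ridge = 1e-6) {
  if (!identical(colnames(pos_features), colnames(neg_features))) {
    stop("feature schema mismatch between groups")
  }
  if (nrow(pos_features) < 2 || nrow(neg_features) < 2) {
    stop("each group needs at least 2 samples")
  }
  all_x <- rbind(pos_features, neg_features)
  mu <- colMeans(all_x)
  sdev <- apply(all_x, 2, stats::sd)
  sdev[sdev == 0] <- 1
  xp <- sweep(sweep(pos_features, 2, mu), 2, sdev, "/")
  xn <- sweep(sweep(neg_features, 2, mu), 2, sdev, "/")
  cp <- sweep(xp, 2, colMeans(xp))
  cn <- sweep(xn, 2, colMeans(xn))
  sw <- crossprod(cp) + crossprod(cn)
  p <- ncol(sw)
  lambda <- ridge * sum(diag(sw)) / p
  sw_reg <- sw + diag(lambda, p)
  delta <- colMeans(xp) - colMeans(xn)
  w <- tryCatch(solve(sw_reg, delta),
                error = function(e) stop("singular within-class scatter ",
                                         "after regularisation: ",
                                         conditionMessage(e)))
  ld1_pos <- drop(xp %*% w)
  ld1_neg <- drop(xn %*% w)
  if (mean(ld1_pos) < mean(ld1_neg)) {
    w <- -w; ld1_pos <- -ld1_pos; ld1_neg <- -ld1_neg
  }
  structure(list(ld1_pos = ld1_pos, ld1_neg = ld1_neg,
                 direction = stats::setNames(w, colnames(pos_features))),
            class = "lda_result")
}

#' Within-group LD1 compactness test
#'
#' Computes every within-group pairwise absolute LD1 difference (n(n-1)/2 per
#' group) and compares the two distance samples by Welch's two-sided t-test:
#' a group whose scores cluster tightly has systematically smaller pairwise
#' distances.
#'
#' @param result \code{lda_result} from \code{lda_ld1}.
#' @return list with \code{t} (statistic, positive when the positive group is
#'   LESS compact), \code{p_value}, and the two distance vectors.
#' @export
ld1_compactness_test <- function(result) {
  if (length(result$ld1_pos) < 2 || length(result$ld1_neg) < 2) {
    stop("each group needs at least 2 scores")
  }
  d_pos <- as.numeric(stats::dist(result$ld1_pos))
  d_neg <- as.numeric(stats::dist(result$ld1_neg))
  spread <- function(d) if (length(d) < 2) 0 else stats::sd(d)
  if (spread(d_pos) == 0 && spread(d_neg) == 0 &&
      mean(d_pos) == mean(d_neg)) {
    return(list(t = 0, p_value = 1, distances_pos = d_pos,
                distances_neg = d_neg))
  }
  tt <- stats::t.test(d_pos, d_neg, alternative = "two.sided",
                      var.equal = FALSE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       distances_pos = d_pos, distances_neg = d_neg)
}

#' Per-family mapping summary
#'
#' Counts, for each miRNA family present among the records, how many members
#' were mapped (appear in the record list) and what fraction of the family's
#' total membership that represents.
#'
#' @param records \code{mirna_records} with a \code{family} annotation.
#' @param family_map named integer vector: total member count per family;
#'   must cover every family present.
#' @return data.frame with \code{family}, \code{n_mapped}, \code{family_size},
#'   \code{fraction}, sorted by decreasing \code{n_mapped}.
#' @export
family_summary <- function(records, family_map) {
  fams <- records$family[!is.na(records$family)]
  if (length(fams) == 0) {
    return(data.frame(family = character(), n_mapped = integer(),
                      family_size = integer(), fraction = numeric()))
  }
  missing <- setdiff(unique(fams), names(family_map))
  if (length(missing) > 0) {
    stop("families missing from map: ", paste(missing, collapse = ", "))
  }
  counts <- table(fams)
  out <- data.frame(
    family = names(counts),
    n_mapped = as.integer(counts),
    family_size = as.integer(family_map[names(counts)]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$fraction <- out$n_mapped / out$family_size
  out[order(-out$n_mapped, out$family), , drop = FALSE]
}
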