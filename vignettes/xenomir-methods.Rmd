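---
title: "Methods: sequence-based discrimination of plant-derived xenomiRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based discrimination of plant-derived xenomiRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Some plant miRNAs — "xenomiRs" — are repeatedly detected in human and animal
samples after dietary intake, while the vast majority of plant miRNAs never
are. One explanation is selective absorption: only miRNAs whose sequences
carry certain compositional patterns survive the gastrointestinal tract and
enter circulation. If that is true, the detected and never-detected classes
should be statistically separable from sequence alone, and a classifier
trained on them should be able to nominate further candidates from the
unlabeled body of known plant miRNAs.

`xenomir` implements that whole argument as a tested pipeline: curation of
labeled sequence sets, a fixed 129-feature sequence encoding, per-feature
hypothesis testing with FDR control, linear-discriminant separability
analysis, two classifiers (a random forest over hand-crafted features and a
small 1-D convolutional network over the raw one-hot sequence), and a
conservative both-models consensus rule for nominating candidates. A
synthetic sequence generator with planted class differences makes every
stage testable end to end without any external download.

## Sequence encoding

Each mature miRNA is encoded as 129 named features:

* **length** — the untruncated sequence length in nt;
* **positional identities** (`pos01`..`pos24`) — the nucleotide at each of
  the first 24 positions, with a gap symbol `-` past the end of the
  sequence. Sequences longer than 24 nt are truncated *for these features
  only*. These are categorical, used for composition profiles, and are
  excluded from all hypothesis tests and model inputs;
* **full-sequence k-mer frequencies** — all 4 one-mers, 16 two-mers and 64
  three-mers, each counted over sliding windows and divided by the window
  count `length - k + 1`, so each k-mer family sums to exactly 1;
* **seed-region k-mer frequencies** (suffix `_seed`) — one- and two-mers of
  the 7-nt seed region (positions 2–8, the target-recognition segment),
  denominators 7 and 6.

The 105 numeric features (length + 84 + 20) form the model schema used by
the statistics stage and the random forest. The window-count denominator is
a declared convention: it makes every k-mer family a proper frequency
distribution, and at k = 1 it coincides with count/length.

The convolutional network instead reads the raw sequence: the first
L = 18 nt are one-hot encoded position-major (`0001` = A, `0010` = C,
`0100` = G, `1000` = U; all-zero blocks pad sequences shorter than L), a 72-bit
vector per miRNA interpreted by the network as an 18-step, 4-channel
signal. L = 18 is the shortest common mature-miRNA length, so for typical
18–24-nt miRNAs the network sees a truncated prefix and **no length
information** — a structural asymmetry against the feature-based model that
matters below.

## Feature screening

`compare_feature_groups()` runs a two-sided Wilcoxon rank-sum test per
feature between the classes and controls the FDR across the 105 tests by
Benjamini–Hochberg, flagging features at FDR < 0.01. The exact null
distribution is used when both groups have at most 25 samples and the
feature is tie-free; otherwise the normal approximation with tie and
continuity correction (k-mer frequencies are heavily tied, so large-sample
screens effectively always use the corrected approximation). Group means
are reported alongside so effect direction is visible.

## LDA separability and compactness

`lda_ld1()` computes the two-class Fisher discriminant on the 105 features,
standardised to zero mean and unit variance. Because each k-mer family sums
to 1, the within-class scatter is rank-deficient; a ridge term
λ = 1e-6 · trace(S~w~)/105 is added to its diagonal before solving. LD1 is
oriented so the positive class has the larger mean. Compactness is compared
as described in the source protocol: all within-group pairwise absolute LD1
differences (n(n−1)/2 per group) are treated as two samples and compared by
a two-sided Welch t-test. Pairwise distances are of course not independent
observations; the test is reproduced as specified and its p-value should be
read as descriptive, not inferential.

## Classifiers and evaluation protocol

**Split.** `split_train_test()` holds out round(0.15 · P) positives (round
half up) and the *same number* of negatives, uniformly at random; with the
study sizes 166/942 this is a 25+25 test set over a 141/917 training set.

**Oversampling.** The positive training class is enlarged to the negative
count as one copy of every positive plus draws with replacement, so every
positive appears at least once and the training set is exactly balanced. In
cross-validation (stratified, 5-fold by default) oversampling happens only
after the validation fold is removed, so a validation sample can never be
duplicated into training; `cross_validate()` asserts this per fold.

**Random forest.** 501 trees, 6 candidate features per split (Gini
criterion), via the `randomForest` package, with importance bookkeeping on.
`rf_importance()` reports mean decrease accuracy (out-of-bag permutation,
averaged over trees) and mean decrease Gini, flagging the top
ceil(10%) = 11 features under each.

**1-D CNN.** Implemented from scratch in base R (no deep-learning framework
is required): two valid-mode convolutions over the 18×4 signal, flatten,
two dense layers, a two-unit softmax; sigmoid activations on all hidden
layers; inverted dropout and L2 weight decay on the dense layers;
categorical cross-entropy minimised by Adam; Glorot-uniform initialisation.
The backpropagation is verified in the test suite against central finite
differences. Defaults — channels (16, 32), kernels (8, 4), dense (64, 32),
dropout 0.3, λ = 1e-3, 100 epochs, batch 32, learning rate 1e-3 — are
exposed in `cnn_config()`; `tune_cnn_random()` offers a seeded random search
over these settings on an internal validation split, a deliberate
lightweight replacement for full Bayesian optimisation. Training is exactly
reproducible from the config seed (all randomness flows through R's RNG).

**Metrics.** `evaluate_scores()` computes the confusion at a 0.5 threshold
(score ≥ threshold calls positive), SN = tp/(tp+fn), SP = tn/(tn+fp),
accuracy, MCC (defined 0 when a denominator factor vanishes) and AUC as the
Mann–Whitney rank statistic with mid-rank tie handling; the ROC curve is
traced over all score thresholds. Each of these is cross-checked in tests
against brute-force pair counting and an independent ROC implementation.

**Consensus.** `predict_consensus()` scores an unlabeled pool with both
models and nominates only sequences called positive by both. The
intersection can never exceed either single call set, and raising any
threshold can only shrink calls — both properties are asserted in tests.

## The synthetic generator

`generate_sequence()` draws a length from a categorical distribution over
18–24 nt, emits nucleotides i.i.d. from a class-specific distribution, then
with a per-motif probability overwrites a planted motif at a uniform random
offset. This zero-order-plus-overwrite design was chosen over Markov chains
because every planted effect size is directly controllable and the expected
feature shifts are computable in closed form for tests.
`table1_like_config()` encodes the reported direction of the real class
differences: positives get C emission 0.26 vs 0.20, U 0.24 vs 0.28, the
motif CAG planted with probability 0.6 vs 0.15, and a length distribution
about 1 nt shorter; class sizes default to 166/942 with a 3695-sequence
unlabeled pool of which 15% come from the positive generator (their truth
labels are carried only to score consensus precision; models never see
them). `null_config()` shares one generator between the classes and
calibrates the pipeline's false-positive behaviour.

What the generator does *not* emulate: miRNA biogenesis constraints (5'-U
bias, Dicer cleavage signatures), family structure and shared precursors,
positional dependence between neighbouring nucleotides, and read-abundance
noise. Passing the recovery tests therefore shows the pipeline detects
compositional differences of the planted kind and does not hallucinate
signal in their absence — it does not certify performance on real miRNA
collections.

## Numerical choices and degenerate inputs

* Deduplication keeps the first occurrence in input order; curation's
  bottom-30% abundance cut removes exactly floor(0.3·n) records per sample
  with abundance ties broken by lexicographic sequence order, so results
  are permutation-invariant.
* T is silently normalised to U on input; any other non-ACGU character
  rejects that record (with a reported id), not the whole file.
* Identical feature vectors in both groups yield p = 1, not an error; a
  group pair whose LD1 scores coincide yields compactness t = 0, p = 1.
* MCC returns 0 on degenerate confusions; AUC requires both classes and
  errors otherwise.
* One global seed in `run_full()` derives the split, oversampling, fold
  and model seeds by fixed offsets, so a run is reproducible end to end.

## Problem sizes used by the stochastic calibrations

The multi-seed calibrations run at sizes chosen to keep a full suite run
comfortable on a single CPU while leaving the estimates stable: the
null-AUC band averages 10 seeds at 80/200 sequences with 30-epoch CNN fits;
the consensus-precision property averages 10 seeds at 120/400 with a
400-sequence pool; the feature-screen null calibration averages 20 seeds at
the full 166/942. The single-split parameter-recovery run and the
acceptance script use the full study sizes (166/942, pool 3695, 100-epoch
CNN).

## Known limitations

* The CNN's input is strictly poorer than the feature schema on this
  generator: it sees only the first 18 nt, hence no length signal (all
  generated lengths are ≥ 18) and no 3'-end composition. On synthetic data
  whose planted effect partly lives in length, the CNN's attainable
  accuracy is structurally below the random forest's, and the recovery
  tests reflect that asymmetry.
* Wilcoxon tie handling and the FDR method are conventions; other
  reasonable choices shift significant-feature counts by small amounts.
* The compactness t-test inherits the dependence problem noted above.
* Scores from a forest trained on an oversampled balanced set are not
  calibrated probabilities on the original class balance; the 0.5 call
  threshold is a convention shared by both models, and per-model thresholds
  are exposed where calibration matters.
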