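Package: xenomir
Title: Sequence-Based Discrimination of Plant-Derived Dietary miRNAs (xenomiRs)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the sequence specificity of plant-derived
    xenomiRs (plant miRNAs detectable in animal bodies). Implements a
    129-feature k-mer and positional encoding of mature miRNA sequences,
    Wilcoxon rank-sum feature screening with Benjamini-Hochberg FDR control,
    Fisher linear discriminant separability and compactness analysis, a
    random forest and a small one-dimensional convolutional network trained
    under an oversampling-inside-cross-validation protocol, and a
    both-models consensus rule for nominating candidate xenomiRs from an
    unlabeled miRNA pool. Includes a synthetic sequence generator with
    planted compositional class differences so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
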