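Package: motifgrammar
Title: Motif-Grammar Classification of Transcription-Factor Binding Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate protein-protein interactors of an anchor
    transcription factor from genome-wide DNA-binding peak sets. Peaks and
    matched random background intervals are scored against a position weight
    matrix (PWM) library by log-likelihood scanning on both strands, turned
    into motifs-per-kilobase feature matrices, and classified with an
    L1-regularized logistic model whose penalty is compressed by a
    knowledge-based rule: shrink until just before the anchor factor's own
    motif would leave the model. Includes replicate-concordance analysis
    (cross-prediction and unique/shared peak partitions), motif co-occurrence
    and anchor-exclusive statistics for indirect-binding candidates,
    comparator classifiers (linear max-margin, random forest), and a fully
    seeded synthetic-data generator with planted motif ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    Matrix,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
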