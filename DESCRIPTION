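Package: qsppred
Title: Prediction and Sequence Analysis of Quorum Sensing Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequence-based analysis and prediction of bacterial quorum
    sensing peptides (QSPs). Converts variable-length peptides into
    fixed-length feature encodings (amino acid and dipeptide composition,
    terminal one-hot binary profiles, AAindex-derived physicochemical
    descriptors and their hybrids) and trains radial-basis-function
    support vector machine classifiers with stratified 10-fold
    cross-validation, reporting sensitivity, specificity, accuracy,
    Matthews correlation coefficient and ROC/AUC. Also provides
    ProtParam-style property calculators (aromaticity, instability index,
    isoelectric point, molecular weight, GRAVY), bracket-class motif
    scanning with positive-predictive-value and coverage evaluation,
    residue composition and positional enrichment analyses, single-position
    mutant design, sliding-window protein scanning, and a synthetic
    peptide-set generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    kernlab,
    pROC,
    withr
Config/testthat/edition: 3
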