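Package: hydroMHC
Title: Hydrophobicity-Stratified Auditing of Peptide-MHC Class I Binding
    Predictors
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for auditing peptide-MHC class I binding predictors for
    hydrophobicity bias. Scores peptide hydrophobicity with side-chain
    scales (Moon scale by default), extracts empirical strong-binder score
    thresholds from predictor output, computes confusion matrices, ROC/AUC
    and accuracy/precision/recall/F1 stratified by hydrophobicity class,
    and compares predicted immunopeptidomes with two-sample t-tests. A
    synthetic-data module simulates anchor-motif-driven binding for common
    HLA alleles, bimodal binding-affinity/eluted-ligand training scores,
    random proteomes, and predictors with a tunable hydrophobicity bias,
    so that hydrophobic false positives and hydrophilic false negatives
    can be injected and recovered end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Biostrings,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Software, Proteomics, ImmunoOncology, Classification
RoxygenNote: 7.3.3
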