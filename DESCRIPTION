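Package: prmpanel
Title: Targeted Serum Proteomics Assay Design and Diagnostic Panel Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for parallel reaction monitoring (PRM) biomarker studies:
    rule-based proteotypic peptide, precursor-charge and transition
    selection with a pluggable detectability/retention-time predictor;
    log10 peak-area normalization anchored on stable-isotope-labeled
    reference peptides with batch-median correction; stable-isotope
    quantification; univariate and OPLS-DA differential statistics with
    VIP scores; candidate biomarker bank assembly; recursive feature
    elimination with cross-validated logistic regression for diagnostic
    panel construction; and confusion-matrix/ROC metric reporting.  A
    synthetic serum-cohort generator with planted group and batch effects
    supports end-to-end validation and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
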