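Package: hlapresent
Title: HLA Class I Antigen-Presentation Prediction from Immunopeptidomics Data
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts presentation of 8-11mer peptides by HLA class I
    molecules from mass-spectrometry (MS) elution data. Provides one-hot
    peptide encoding with 'Z' padding, class-rebalanced per-allele training
    of an inception-style convolutional classifier, decoy-based benchmarking
    with sensitivity/specificity/positive predictive value, percentile-rank
    thresholding and intersection ensembles with an external predictor,
    position-frequency-matrix motif and anchor-residue analysis, and
    sliding-window extraction of neoantigen candidate peptides from driver
    missense mutations. Includes seeded synthetic generators for
    motif-governed peptide datasets, toy proteomes and mutation tables so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
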