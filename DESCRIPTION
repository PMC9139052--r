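Package: dhtppi
Title: Sequence-Based Protein-Protein Interaction Prediction with
    Hilbert-Transform PSSM Descriptors and Rotation Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts protein-protein interactions (PPIs) from sequence
    alone. Each protein is represented by a position-specific scoring
    matrix (PSSM), featurized through a two-dimensional discrete Hilbert
    transform (DHT) into a 200-dimensional evolutionary-conservation
    descriptor; a protein pair is the 400-dimensional concatenation.
    Pairs are classified by a from-scratch Rotation Forest ensemble
    (per-subset PCA rotations over bootstrap samples, decision-tree base
    learners, mean-combination prediction) and evaluated under stratified
    five-fold cross-validation (accuracy, sensitivity, specificity,
    precision, Matthews correlation coefficient, ROC/AUC). Includes
    readers for FASTA and PSI-BLAST ASCII PSSM files, a substitution
    matrix pseudo-PSSM fallback, and a planted-signal synthetic data
    generator so the full pipeline is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
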