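Package: phosphobind
Title: Predict Phosphosites Bound by Phosphoprotein-Binding Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of phosphoprotein-binding-domain (PPBD)
    specific binding phosphosites (PBSs) from protein sequence. Implements
    group-based peptide similarity scoring against a positive peptide set with
    a BLOSUM62 substitution matrix, position-weight optimization by L1-penalized
    logistic regression followed by randomized hill climbing under a
    cross-validated AUC objective, a 231-dimensional unordered residue-pair
    similarity encoding of peptides, a small feed-forward neural classifier
    trained hierarchically (group to family to single-domain cluster) by
    transfer learning, false-positive-rate calibrated decision thresholds
    against random background peptides, and a permutation test for
    co-regulation of phosphosites by binding-domain and kinase families,
    with hypergeometric enrichment of annotation terms. A seeded synthetic
    motif generator makes the whole pipeline testable without external data.
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
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
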