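Package: comutmap
Title: Co-Occurrence and Mutual Exclusivity Mapping of Somatic Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection of significantly co-occurring and mutually exclusive
    mutated gene pairs in tumor cohorts. Builds binary gene-by-sample mutation
    matrices from MAF-like somatic variant tables (with functional-consequence
    filtering, overlapping-gene resolution and hypermutator removal), tests all
    gene pairs with a fixed-margin matrix-permutation null model and with a
    fast weighted-resampling (WeSME-style) approximation, controls the false
    discovery rate empirically from permutation-derived null P-value sets,
    selects high-confidence candidates across replicate runs, and screens
    candidates for mutation-load-association confounding via logistic
    regression. A synthetic-cohort generator with planted interactions and a
    known truth table makes every stage testable without access to controlled
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
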