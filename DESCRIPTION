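Package: rarecf
Title: Collaborative Filtering on Heterogeneous Phenotype Data for Rare
    Disease Diagnosis Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: User-based collaborative filtering over binary phenotype
    profiles to rank candidate rare-disease diagnoses. Patient profiles
    from electronic medical records and per-disease merged literature
    documents are fused under three strategies (EMR only, raw mix, and
    EMR-pruned literature), neighbors are found with four binary set
    similarity measures (Tanimoto, overlap, Fager-McGowan, and a
    log-likelihood-ratio similarity) under k-nearest-neighbor or
    threshold neighborhoods, and ranked recommendations are evaluated
    with precision-recall curves, mean average precision, and
    per-disease F-measures under string, concept, and category disease
    matching. Includes a synthetic-cohort generator with planted disease
    signatures for benchmarking and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
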