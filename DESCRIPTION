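Package: entnorm
Title: Dictionary-Based Entity Normalization for Drug Names and Cancer Types
Version: 0.1.0
Authors@R:
    person("Entnorm", "Developers", email = "entnorm@example.org", role = c("aut", "cre"))
Description: Fast, dictionary-based normalization of biomedical entity names
    (drug names, cancer types) to reference identifiers such as ChEMBL
    accessions or Disease Ontology terms. Queries pass through a cascade of
    matchers of increasing cost: exact lookup of the preprocessed name,
    order-invariant token matching, word n-gram containment, and normalized
    Levenshtein edit-distance matching under a user-set threshold. Includes
    loaders for OBO-format ontologies (with subtree restriction, e.g. to the
    cancer subtree rooted at DOID:162) and delimited synonym tables, a
    precision/recall/F1 evaluation harness with bootstrap resampling, a
    seeded synthetic gold-standard generator with known ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stringi,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
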