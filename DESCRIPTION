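Package: scmfdd
Title: Similarity-Constrained Matrix Factorization for Drug-Disease
    Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts unobserved drug-disease associations by factorizing a
    binary association matrix into low-rank drug and disease latent factors
    under graph-based similarity constraints (SCMFDD). Includes drug-drug
    Jaccard similarity from binary descriptor fingerprints, disease-disease
    semantic similarity from MeSH tree-number hierarchies, an alternating
    exact row-Newton optimizer for the constrained factorization, five-fold
    cross-validation with AUPR-centric metrics, a planted-low-rank synthetic
    data generator for self-contained testing, and delimited-text readers and
    writers with a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
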