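Package: stpmatch
Title: Signal Transduction Pathway Activity Scoring and
    Patient-Representative Cell Line Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signal transduction pathway (STP) activity scores from
    target-gene expression with a two-layer Bayesian network, normalizes
    them to a 0-100 odds scale, clusters cell-line STP profiles, and
    characterizes clusters and histological subtypes with nonparametric
    tests. Tumor STP profiles are matched to their nearest cell line by
    least squares to rank patient-representative cancer cell line models.
    Includes a synthetic-cohort generator with known ground-truth pathway
    activity so every pipeline stage can be exercised without external
    expression data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
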