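Package: pathcomorbid
Title: Pathway-Space Disease Overlap, Comorbidity and Expression Dysregulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates disease genetics with clinical and molecular data at
    the level of biological pathways. Builds a gene-by-gene shared-pathway
    matrix from disease-gene association catalogs and KEGG-style gene sets,
    tests disease pairs for overlap in pathway space with a one-tailed
    Wilcoxon rank-sum test, computes per-disease pathway loads and correlates
    them with Alzheimer's disease comorbidity ratios estimated from matched
    hospital-discharge records, tests pathway-level expression dysregulation
    with per-gene logistic models and an exact binomial enrichment test, and
    quantifies qPCR experiments by the 2^-ddCT method. A synthetic-data
    generator with plantable effects provides parameter-recovery and
    calibration tests for every stage, so the full pipeline runs without any
    external data snapshot.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
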