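Package: stagetraffic
Title: Spermatogenesis Stage Classification and Chromosomal Traffic of New Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cell-level analysis of new-gene evolution during Drosophila
    spermatogenesis. Aggregates a labeled single-cell count matrix into
    per-gene, per-cell-type pseudobulk profiles, classifies genes into
    spermatogenesis stage categories (mitosis through post-meiosis) by
    row-scaled hierarchical clustering, quantifies per-chromosome enrichment
    of stage categories with Fisher exact tests and normalized ratios, scores
    the stage shift between parental and new genes ("into the meiosis"), and
    tests the "out of the X" excess of retroposed genes against a
    gene-number-by-chromosome-size null. A negative-binomial synthetic-data
    generator with planted stage archetypes and route-biased shifts makes the
    full pipeline testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
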