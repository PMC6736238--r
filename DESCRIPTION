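Package: genecascades
Title: Gene Cascade Reconstruction from Wild-Type Versus Mutant Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts gene cascades downstream of a translational-regulator
    query gene from a wild-type versus mutant expression table (RPKM) and
    flat-file annotation extracts. Genes are classified as fluctuating or
    stable by the median plus or minus quartile deviation of the
    mutant/wild-type expression ratio; direct targets are stable
    transcription factors sharing expression timing and mutant phenotype
    with the query; each target is expanded into a cascade by iterative,
    life-stage-filtered traversal of regulatory, genetic, and physical
    interaction edges; cascade bottom genes are scored for protein-domain
    over-representation with a binomial tail test and aggregated into
    functional-category scores. Includes a seeded synthetic-data generator
    with planted ground-truth cascades and Cytoscape-compatible network
    export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
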