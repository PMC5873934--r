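Package: stressPrio
Title: Cross-Species Multiple-Stress Candidate Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for prioritizing candidate genes for
    multiple abiotic stress tolerance in sorghum and related model species.
    Combines multi-ontology (GO/TO/PO/GRO/EO) semantic screening with direct
    and ortholog-transitive annotation transfer, hypergeometric gene-set
    enrichment with Benjamini-Hochberg FDR gating, two-group differential
    expression with fold-change gating, cross-stress and cross-species gene-set
    partitioning, gene-QTL interval co-localization, and neighbor-joining
    phylogenetics with bootstrap support. Includes seeded synthetic-data
    generators so every stage is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
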