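Package: catego
Title: Category-Level Gene Ontology Enrichment and Data Exploration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Species-agnostic Gene Ontology (GO) enrichment analysis over
    curated high-level term categories, with two statistical engines
    (Fisher's exact test over candidate gene lists with Benjamini-Hochberg
    adjustment, and the Mann-Whitney U test with delta ranks over gene lists
    carrying a continuous measure), per-term zoom without adjustment,
    multi-set Venn partitioning with iterative backgrounds, a heat-map
    result store for cross-analysis comparison, and interaction-network
    exploration with breadth-first connector search, GO-graph semantic edge
    lengths and receptor-ligand cross-dataset pairing. Includes a
    deterministic synthetic-fixture generator (toy ontologies, annotation
    tables, candidate and measured gene lists with planted signals, toy
    interactomes) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
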