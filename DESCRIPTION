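Package: membranomics
Title: Ontology Enrichment, Tree Mining and Network Statistics for
    Subcellular Proteomes
Version: 0.1.0
Authors@R:
    person("Membranomics", "Developers", email = "membranomics@example.org",
           role = c("aut", "cre"))
Description: Systems-analysis toolkit for subcellular proteomes such as the
    luminal endothelial-cell plasma-membrane proteome ("membranome").
    Provides an OBO ontology store with true-path annotation propagation,
    hypergeometric Z-score over-representation statistics with exact tail
    probabilities, recursive category-tree mining that reports terminal
    ("actual") enriched functions, P/H label-free quantification ratio
    classification, protein-interaction network construction and scoring,
    and a fully seeded synthetic-data generator so every pipeline stage is
    testable at desk scale without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
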