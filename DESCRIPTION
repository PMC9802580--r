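Package: comorbnet
Title: Network-Based Comorbidity Analysis of Disease-Associated Kinases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for network-based comorbidity screens built around a
    disease-associated kinase set: seed-gene selection by database
    intersection and literature union, protein-protein interaction (PPI)
    and bipartite (disease/miRNA/drug versus kinase) network construction,
    degree and betweenness (Brandes) hub ranking, top-k agent coverage
    prioritization, hypergeometric over-representation testing with
    Benjamini-Hochberg adjustment, and median-split Kaplan-Meier survival
    analysis with a log-rank test. Ships a fully seeded synthetic-data
    generator with planted structure so that every pipeline stage can be
    verified against a known ground truth without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
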