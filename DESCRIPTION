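Package: netpharm
Title: Network-Pharmacology Target Screening for Multi-Herb Formulas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reproducible re-implementation of the network-pharmacology
    screening workflow used to nominate core and hub therapeutic targets of a
    multi-herb formula against a disease: ADME-based ingredient screening with a
    literature whitelist, compound-target bipartite network construction,
    protein-protein interaction subnetwork expansion and intersection, two-stage
    median-centrality topological screening with top-k hub selection,
    hypergeometric over-representation analysis, and docking-energy ranking.
    Includes fixed-seed synthetic generators (scale-free interactomes, compound
    tables, multi-cohort expression data with planted differential expression,
    gene-set collections) so the whole pipeline runs without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
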