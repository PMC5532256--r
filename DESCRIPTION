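Package: markeval
Title: Literature and Network Metrics for Disease Candidate Gene Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative evaluation of disease candidate genes from curated
    literature evidence and pathway annotation. Computes two literature-based
    scores per gene (reference support count and publication age), performs
    Fisher-exact gene-set enrichment with Benjamini-Hochberg false discovery
    control, builds a pathway co-membership gene-gene interaction network,
    and scores genes by generalized (alpha-) weighted degree centrality.
    Any resulting gene ranking can be validated on independent case/control
    expression data with a nearest-centroid leave-one-out classification
    sweep and a permutation test. Includes a synthetic-data generator that
    emulates the statistical structure of curated gene-disease relation
    tables, overlapping gene-set collections, and case/control expression
    matrices with planted signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
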