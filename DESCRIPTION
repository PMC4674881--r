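Package: sigreach
Title: Reachability-Based Characterization of Probabilistic Signaling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing signaling networks whose interactions
    carry existence probabilities. Computes the exact probability that a
    signal propagates from receptor (source) to reporter (target) nodes by
    multiplying per-edge binomials into an xy-polynomial and collapsing
    decided terms at path or cut events; derives a probabilistic node
    centrality from per-pair essentiality probabilities; measures network
    stability under edge-probability perturbation and degree-preserving
    topology shuffling; and characterizes network functions by
    hypergeometric enrichment of annotation terms among the most reachable
    targets and by per-term reachability, with hierarchical clustering of
    reachability matrices. Includes seeded generators for layered synthetic
    networks and annotation tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
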