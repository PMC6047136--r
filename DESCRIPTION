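Package: netlinkpred
Title: Link Prediction and Module Detection for Drug-Target and
    Protein-Protein Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts missing links in bipartite drug-target networks and
    unipartite protein-protein networks. Implements bipartite recommenders
    (HeatS heat conduction, network-based inference mass diffusion, random
    walk with restart on a heterogeneous drug/target network, and their
    combination), nine neighborhood and five path-based unipartite link
    predictors, LP-BRIM bipartite community detection with Barber
    modularity, Yen's top-K loopless shortest paths, degree-preserving
    permutation significance testing, and a link-removal benchmark scored
    with AUAC, AUC, truncated AUC, BEDROC and enrichment factor. A seeded
    generator for bipartite networks with planted module structure and
    profile-correlated similarity matrices supports fully offline testing,
    and a command-line interface exposes every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
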