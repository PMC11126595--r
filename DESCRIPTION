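Package: biplink
Title: Balanced Link Prediction and Evaluation for Bipartite Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for neighbourhood-based link prediction in two-mode (bipartite)
    association networks such as probiotic-disease networks. Implements balanced
    two-sided variants of the common-neighbours, Jaccard, Adamic/Adar and
    preferential-attachment ranking scores built on the neighbour-of-neighbour
    set Gamma(Gamma(x)), together with k-fold edge-holdout cross-validation,
    the sampled-pair AUC and precision-at-L evaluation metrics, descriptive
    network statistics, and seeded generators for synthetic bipartite networks
    with heavy-tailed degrees and optional planted block structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Matrix,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
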