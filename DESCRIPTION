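Package: dlsnet
Title: Discriminative Local Subspaces for Gene Function Prediction
Version: 0.1.0
Authors@R: person("DLS", "Maintainers", email = "dlsnet@example.org",
    role = c("aut", "cre"))
Description: Predicts genes involved in a biological process of interest from
    log-ratio gene-expression compendia. Training sets are derived from an
    ontology DAG with upward annotation propagation; a greedy local-subspace
    feature search (signFS) finds, for each positive gene, the subset of
    experimental comparisons on which it is strongly co-expressed with other
    positives and weakly with negatives; predictions are scored by Bayes rule
    with kernel density estimates of class-conditional co-expression and
    assembled into a directed, confidence-weighted discriminative
    co-expression network. Includes RankProducts-based preprocessing of
    replicated intensity data, an iterative false-negative discovery
    procedure for noisy negative labels, a cross-validation and enrichment
    evaluation harness with a co-expression-network baseline, and a
    synthetic-data generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
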