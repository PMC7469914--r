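Package: syntrader
Title: Synthetic Drug Repurposing with Association Rules and the Trader
    Discrete Optimizer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for synthetic drug repurposing: replacing a single drug
    with a combination of approved drugs that jointly cover its disease
    relevant targets with fewer total side effects. Implements If-Then
    association rules over drug-target interaction matrices to mine
    candidate drugs, the Trader discrete metaheuristic (population of
    binary candidate solutions organized into trader groups, evolved by
    retailing, distributing and importing-exporting operators under an
    evaluation budget), exact exhaustive oracles and generic baseline
    optimizers, a weighted chemical-formula similarity score, synthetic
    benchmark instance generators with planted optima, and a benchmarking
    harness with convergence, stability and Wilcoxon rank-sum statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
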