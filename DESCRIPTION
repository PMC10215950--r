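Package: causalstab
Title: Robustness of Learned Causal Structures under Leave-k-Out Resampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constraint-based causal structure learning for categorical
    genotype data (PC-stable skeleton search with G2 or symmetric
    likelihood-ratio conditional independence tests, v-structure orientation
    and Meek completion to a CPDAG, Markov blanket extraction), customized
    graph-comparison metrics (edge-overlap categories, structural Hamming
    distance and its relative form), and a three-pillar leave-k-out
    resampling pipeline that quantifies the global and local stability of a
    learned structure when patients are randomly excluded from the dataset.
    Includes a discrete Bayesian-network simulator with a plantable outcome
    Markov blanket so the whole pipeline is testable against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    nnet,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite
Config/testthat/edition: 3
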