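Package: vamix
Title: Vector-Attribute Assortativity for Networks via Randomization Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies assortative mixing in undirected networks whose nodes
    carry vector-valued attributes. Implements the VA-index, a bounded (-1, 1)
    effect-size measure obtained by comparing the observed mean edge
    similarity against a Monte-Carlo null distribution from graph
    randomization (uniform G(n,m), degree-preserving edge swaps, or
    covariate-matched rewiring), together with an empirical two-sided
    permutation test. Also provides the classic scalar assortativity
    coefficient, a per-dimension-average baseline for vector attributes, a
    planted-partition synthetic benchmark generator with known ground-truth
    mixing, and an evaluation harness (RMSE, absolute-error differences,
    estimator bias/variance). Includes a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    MASS,
    withr,
    jsonlite,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, StatisticalMethod
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'similarity.R'
    'assortativity.R'
    'randomization.R'
    'vaindex.R'
    'synthetic.R'
    'evaluation.R'
    'cli.R'
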