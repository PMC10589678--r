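Package: stochnet
Title: Stochastic Generative Network Models of the Developing Connectome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the growth of binary brain networks under a
    distance-penalty / homophily (matching-index) wiring rule, and quantifies
    the developmental consequences of stochasticity in that growth process.
    Provides consensus-network and rich-club tools for building empirically
    grounded seed networks, repeated-run parameter sweeps over the wiring
    exponents, topological and embedding dissimilarity landscapes
    (multifinality), timed noise-injection experiments, communicability-based
    attack-robustness analysis, pairwise SVM distinguishability of parameter
    combinations (equifinality), and Kolmogorov-Smirnov energy landscape
    fitting of wiring parameters to connectome cohorts with group-comparison
    statistics. Synthetic cohort generators allow every stage to be exercised
    without access-restricted neuroimaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    e1071,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
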