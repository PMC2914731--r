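Package: qsperm
Title: Robust Median-Spline Permutation Tests for Time-Course Gene
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies genes whose expression time-trajectories differ
    among K groups using median (quantile) regression splines fitted by
    linear programming, an F-type goodness-of-fit statistic, a
    within-time-point permutation null distribution, and single-step maxT
    adjustment to control the family-wise error rate, with
    Benjamini-Hochberg adjusted p-values as an alternative. Includes a
    synthetic time-course generator with symmetric outlier contamination
    and block-exchangeable gene-gene correlation for type-I-error and
    power benchmarking, and thin command-line wrappers for both the test
    and the simulation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1),
    SummarizedExperiment
Imports:
    methods,
    stats,
    graphics,
    utils,
    splines,
    Rcpp,
    jsonlite,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    quantreg,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
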