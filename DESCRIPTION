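Package: feedeval
Title: Genetic Evaluation of Feed Efficiency Metrics in Dairy Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genetic evaluation of feed-utilization efficiency
    in lactating dairy cows. Implements phenotype engineering for energy-sink
    traits (energy-corrected milk, metabolic body weight, body-weight change,
    expected dry-matter intake under a Nordic Red requirement formulation and
    the NRC 2021 prediction equation, energy conversion efficiency), pedigree
    relationship matrices with their sparse inverses and unknown-parent
    groups, VanRaden genomic relationships and single-step H-inverse
    assembly, mixed-model equations for regression-on-expected-feed-intake,
    one-step residual feed intake, multi-trait energy-sink and energy
    conversion efficiency models, exact-trace EM-REML variance component
    estimation, selection-index breeding values (RFI index and
    RZFeedEfficiency), linear-regression forward validation with bootstrap
    standard errors, and a synthetic herd generator that emulates a nucleus
    research-herd feed-intake recording scheme for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
LinkingTo:
    Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
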