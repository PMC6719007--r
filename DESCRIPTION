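Package: fetalfrac
Title: Fetal Fraction Estimation from Cell-Free DNA Fragment Lengths and
    Counts in Non-Invasive Prenatal Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimators of the fetal fraction of cell-free DNA in maternal
    plasma from shallow whole-genome sequencing. Builds fragment-length
    profiles (50-220 bp) from paired-end alignments, computes the
    chromosome-Y reference estimator, corrects binned read counts for GC
    bias, and fits length-profile regressors (interval ratio statistic,
    nonlinear ratio regression, linear regression, linear support vector
    regression, multilayer perceptron). Predictors can be combined with
    sample attributes in a linear model, and low-fetal-fraction samples can
    be up-weighted during training. Includes a synthetic-sample simulator
    and a repeated train/test evaluation harness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    Rsamtools,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
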