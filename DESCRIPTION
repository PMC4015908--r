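Package: pstbias
Title: Bias Correction for Paired Screening Trials with Differential
    Verification
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and bias correction for paired trials of two
    continuous screening tests in which only screen-positive or symptomatic
    participants receive the reference standard test. Implements the binormal
    ROC model, a weighted maximum likelihood correction of the case score
    distribution based on quadrant-truncated bivariate Gaussian estimation
    and sampling fraction weighting, hypothesis tests for the paired
    difference in full areas under the curves, and a Monte Carlo harness
    that quantifies Type I error and correct and wrong rejection fractions
    of the standard (observed), corrected, and omniscient (true) analyses.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mvtnorm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
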