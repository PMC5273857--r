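Package: empnull
Title: Empirical Null Estimation and Bias/Inflation Correction for
    Genome-Wide Test Statistics
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the empirical null distribution of large sets of
    association test statistics (z-scores from EWAS, TWAS, or similar
    feature-by-feature analyses) by fitting a three-component normal
    mixture with a Gibbs sampler.  The mean and standard deviation of
    the null component quantify test-statistic bias and inflation and
    are used to rescale z-scores, p-values, and effect sizes.  Includes
    genomic-control baselines, fixed-effect inverse-variance
    meta-analysis with per-study correction, simulation generators for
    mixture, confounded, and block-correlated test statistics, and a
    false-positive-rate/power benchmark harness.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
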