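Package: cassim
Title: Cassava Crop Growth Simulation with Global Sensitivity and
    Uncertainty Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale mechanistic simulator of cassava (Manihot
    esculenta) growth and development together with the full global
    sensitivity and uncertainty analysis (GSUA) toolchain used to study
    it: truncated probability distributions for genotype-specific
    parameters with Kolmogorov-Smirnov/AIC model selection, a stochastic
    daily weather generator and DSSAT-style WTH file exchange, a
    tipping-bucket soil water balance with a soil-water-content drought
    stress factor, Morris-type elementary-effects screening with enhanced
    sampling uniformity, and Sobol variance decomposition with first- and
    total-order indices and uncertainty summaries across warm/cool and
    rainfed/water-unlimited environments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
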