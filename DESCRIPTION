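Package: molarAge
Title: Forensic Age Prediction from MRI-Segmented Molar Tissue Volumes
Version: 0.1.0
Authors@R:
    person("Forensic", "Biostatistics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for predicting whether a sub-adult is older
    than 18 years from MRI-segmented tooth tissue volumes of first and second
    molars. Provides T2 intensity-threshold voxel quantification, the ten
    ratio transformations of the three tissue volumes with a Pearson
    redundancy screen, a grid of heteroscedastic sex-structured weighted
    linear regressions selected by AIC and ranked by the p-value of the age
    term, Bayesian posterior age densities with a uniform prior and the
    probability of being older than 18, a bivariate-normal model combining
    two molars with a maximum-likelihood correlation parameter, and a
    synthetic cohort generator calibrated to published volume statistics so
    that every stage is testable without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
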