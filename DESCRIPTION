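Package: coarsenCausal
Title: Causal Effect Estimation by Generalized Coarsened Confounding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Stratification ("coarsened confounding") estimators of average
    causal effects from observational data. Confounder strata are built from
    covariates alone by coarsened exact matching, k-means quantization, or
    unsupervised random-forest proximity clustering; average treatment
    effects (ATE) and effects on the treated (ATT) are estimated by
    stratum-weighted mean contrasts with closed-form variance estimators and
    Wald inference. Includes a simulation-extrapolation style correction for
    the finite-strata bias (regress estimates on the reciprocal strata count
    and extrapolate to zero), an L1 covariate-balance diagnostic, a
    synthetic-data generator with known potential-outcome structure for
    validation studies, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
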