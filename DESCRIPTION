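Package: survonet
Title: Nonparametric Conditional Survival Estimation with Time-Varying
    Covariate Histories via Deep Operator Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates the conditional survival function given entire
    histories of external time-varying covariates without proportional
    hazards or instantaneous-effect assumptions.  The log conditional
    hazard is modelled as an operator of the covariate history using a
    deep operator network (a branch net encoding the history sampled at
    m sensors and a trunk net encoding time, combined by a dot product)
    and trained by minimising a discretized full-likelihood loss for
    right-censored data.  Includes a survival simulator with cumulative
    covariate effects, person-period data expansion with future-value
    masking, early-stopped Adam training with hyperparameter search,
    and evaluation by censoring-weighted (integrated) Brier scores with
    K-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
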