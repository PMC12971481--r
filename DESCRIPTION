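Package: birdtwin
Title: Digital-Twin Updating of Bird Occurrence and Vocal Activity Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A continuously updatable ("digital twin") model of bird
    spatiotemporal distributions driven by streaming audio-based citizen
    science detections. The detection probability for a species in a
    recording factors into a migration component (normal-CDF phenology
    curve in day and latitude), a spatial occurrence component (per-cell
    probability surface) and a vocal detection component (periodic
    logistic model translated to app recordings via a probit model).
    The package provides prior-model fitting, three Bayesian MAP
    updaters (probit detection translation, functionally penalized
    migration update, kernel-weighted local-likelihood spatial update
    with truncated-Gaussian priors and Laplace variances), walk-forward
    next-day AUC evaluation, utility-based validation-site selection,
    and a synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
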