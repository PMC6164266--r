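Package: downscaler
Title: Regional Bayesian Downscaling of Satellite AOD to Daily Ground PM2.5
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calibrates gridded satellite aerosol optical depth (AOD) and
    ancillary meteorological and land-use covariates to point-referenced
    daily ground PM2.5 measurements with a hierarchical Bayesian
    spatiotemporal model.  The daily intercept and AOD slope carry
    spatially correlated effects built from two latent Gaussian processes
    through a linear model of coregionalization with a tapered exponential
    covariance, plus independent first-order random-walk daily effects.
    Fitting is by a Gibbs sampler with conjugate block updates and a
    discrete griddy update for the spatial ranges.  The package predicts
    posterior-mean concentration surfaces with uncertainty on the grid,
    blends overlapping buffered regional models into a seamless surface,
    aggregates daily predictions to period means, and evaluates predictions
    by random and spatially blocked 10-fold cross-validation.  A
    synthetic-data generator with known ground truth supports testing and
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    mgcv,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
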