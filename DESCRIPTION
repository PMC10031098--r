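Package: sptdiff
Title: Diffusion Coefficient Estimation for Single-Particle Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating diffusion coefficients from two-dimensional
    single-particle tracking trajectories. Simulates Brownian trajectories
    with static localization noise and camera motion blur, estimates the
    diffusion coefficient per trajectory both by a three-point linear fit to
    the time-averaged mean square displacement and by maximum likelihood
    under a tridiagonal displacement covariance model that separates
    diffusion from localization noise, and provides batch estimation, group
    summaries (mean, SD, coefficient of variation), Kolmogorov-Smirnov group
    comparisons and simulation studies comparing the two estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ggplot2,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
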