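Package: survpoint
Title: Parametric Survival Extrapolation Through Specified Survival
    Coordinates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recovers the parameters of standard parametric survival
    distributions (exponential, Weibull, log-logistic, log-normal,
    Gompertz) so that the survival curve passes exactly through
    user-specified (time, survival) coordinates, by closed-form
    rearrangement of the survival functions or bracketed root finding.
    Solved models can be assembled into health-economic extrapolations:
    piecewise models joining a Kaplan-Meier prefix to a conditional
    parametric tail, mixture cure models, background-mortality hazard
    floors from a life table, model averages, restricted mean survival
    time, and probabilistic sensitivity analysis that recentres a
    data-derived variance-covariance matrix on the interpolated
    parameters.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    graphics,
    optparse,
    stats,
    survival,
    utils,
    yaml
Suggests:
    flexsurv,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
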