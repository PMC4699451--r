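Package: vesiflux
Title: Vesicle Transport Simulation and Point-Process Statistics of
    Sustained Exocytosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying sustained neuroendocrine exocytosis as a
    point process. Provides an overdamped Langevin simulator of vesicles
    diffusing in a sub-membrane volume with an absorbing membrane face and
    an optional attractive harmonic potential, a docking-to-fusion lag-time
    sampler, kernel (density-function) estimation of the release rate,
    the time-rescaling transformation and its inverse, renewal statistics
    (interspike-time and frequency-count histograms with prescribed
    bin-width rules), least-squares fitting of exponential, Poisson, gamma,
    gamma-count and log-normal models with dispersion diagnostics, and a
    synthetic-data generator (gamma-renewal trains under a logistic
    decaying rate, amperometric current traces, threshold spike detection)
    for end-to-end validation of the analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
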