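Package: weibullrelease
Title: Weibull Modelling of Cumulative Drug-Release Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical analysis of in-vitro cumulative drug-release
    profiles with the non-normalized Weibull distribution (the Kohlrausch
    stretched exponential): closed-form model functions and derived time
    statistics, linearization diagnostics (log-log power-law and Weibull
    probability plots), nonlinear least-squares parameter estimation with
    model comparison against classical mechanistic models (zero-order,
    first-order, Higuchi, Korsmeyer-Peppas power law), transport-mechanism
    classification from shape exponents, regulatory dissolution-efficiency
    summaries, and a seeded synthetic release-profile generator for
    estimator validation. Profiles are plain CSV; reports are JSON/CSV; a
    small command-line front end ties the stages into a pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
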