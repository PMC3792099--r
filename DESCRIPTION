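Package: txmsm
Title: Multi-State Comparison of Transplant and Non-Transplant Registry Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing a transplant registry (patients observed only
    from transplant onwards, i.e. left-truncated on the diagnosis time scale,
    with diagnosis-to-transplant waiting times observed under right truncation)
    with a non-transplant registry, via an illness-death multi-state model
    Diagnosis -> Transplant -> Death.  Provides delayed-entry Kaplan-Meier and
    Nelson-Aalen estimators, the reverse-time product-limit estimator for
    right-truncated waiting times, competing-risks cumulative incidence,
    Cox regression on counting-process data with Breslow ties and
    time-varying treatment effects, a proportional-hazards test on scaled
    Schoenfeld residuals, Aalen-Johansen transition probabilities and
    reconstruction of from-diagnosis survival curves for both treatment
    strategies.  A piecewise-exponential illness-death simulator with shared
    frailty and selection-on-risk, together with a replication engine, is
    included to demonstrate and quantify the immortal-time and selection
    biases of naive survival comparisons between such registries.
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
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
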