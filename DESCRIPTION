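Package: enigo
Title: Electrical Neuroimaging Analysis of Go/NoGo Inhibition Experiments
Version: 0.1.0
Authors@R:
    person("Enigo", "Developers", email = "enigo-dev@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis tools for two-group Go/NoGo event-related
    potential (ERP) experiments: simulation of task schedules, behavioral
    trial logs and multichannel EEG epochs with plantable group-by-condition
    effects; signal-detection and mixed-ANOVA behavioral statistics;
    Butterworth filtering, epoching, artifact rejection, trial-count matching
    and spherical-spline channel interpolation; mass-univariate
    electrode-by-time mixed ANOVAs with permutation-calibrated sustained-effect
    criteria; an analytic three-shell spherical head model with a regular
    source grid; a minimum-norm distributed inverse with local
    autoregressive-average (LAURA) regularization; and node-wise source
    statistics with Monte-Carlo-calibrated cluster-extent correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
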