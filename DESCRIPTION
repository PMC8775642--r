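Package: fatiguekit
Title: Muscle Fatigue and Recovery Modelling for Forceful Exertion Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Models the development and recovery of muscle fatigue in
    sustained forceful exertion tasks such as manual demolition work.
    Fits candidate maximum-endurance-time (MET) models (exponential and
    power forms, with or without intercept) by log-linearised least
    squares and selects among them by R-squared; estimates the strength
    recovery rate of an exponential recovery model by regression through
    the origin on log-transformed strength deficits; predicts strength
    at a given rest time and inverts the model in closed form to obtain
    the rest time needed to reach a target fraction of maximum voluntary
    contraction. Ships validation statistics (absolute and relative
    deviation, Pearson correlation, intraclass correlation ICC(2,1),
    Bland-Altman agreement), CSV input/output for trial and recovery
    data, a synthetic cohort generator that emulates the statistical
    structure of a demolition-hammer endurance study, and an end-to-end
    fit/validate pipeline with machine-readable JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
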