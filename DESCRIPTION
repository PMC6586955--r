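Package: lftrack
Title: Linear Feature Tracking Analysis of High-Frequency GPS Bursts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to detect and quantify linear feature tracking (LFT) --
    directed animal movement along roads, forest edges, and streams -- from
    high-frequency GPS burst data. Provides burst segmentation and travel
    filtering (sinuosity and mean speed), proximity-buffer geometry against
    typed polyline features, correlated-random-walk null models with
    conditional logistic path-selection analysis, rule-based LFT event
    detection, time-to-abandonment survival analysis (Kaplan-Meier medians
    with hierarchical bootstrap intervals and stratified Cox contrasts),
    mixed-model analysis of travel speed during tracking, and a two-state
    movement simulator that reproduces the burst schedule, GPS error, and
    behavioural structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    lme4,
    stats,
    survival,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
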