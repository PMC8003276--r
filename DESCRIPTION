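Package: proxisoc
Title: Sociability and Place-Popularity Analytics for Indoor Localization Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify social behaviour of residents in assisted-care
    facilities from coarse-grained indoor localization traces sampled every
    10 seconds. Implements the Relational Index family (raw, continuity-filtered
    via moving median and minimum-duration filtering, individual, community, and
    time-specific adjusted variants), the Popularity Index of places with
    penalized B-spline smoothing of its daily series, feature encodings and two
    small feed-forward neural regressors for predicting community sociability
    and place popularity, the Community Behaviour Prediction Table, and an
    agent-based synthetic trace generator with controllable social structure
    for end-to-end testing without access to sensitive resident data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    mgcv,
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
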