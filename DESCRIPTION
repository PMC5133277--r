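Package: mtverify
Title: Action Dynamics of Cross-Modal Verification Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for two-choice mouse-tracking
    verification experiments crossing stimulus plausibility, sentence-scene
    congruency and modality order. Builds Latin-square stimulus designs,
    simulates cursor trajectories from a two-attractor competition model,
    applies standard trial-exclusion rules, extracts the classic trajectory
    measures (initial degree, movement latency, x-flips, area under the
    curve), and fits contrast-coded maximal mixed-effects models plus a
    growth-curve analysis of time-normalized movement angles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
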