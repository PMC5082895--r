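Package: vmstrips
Title: Identifying, Measuring and Classifying Fishing Trips from Vessel
    Monitoring System Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for resolving individual fishing-vessel trips from sparse,
    gappy vessel monitoring system (VMS) position streams. Cleans raw
    position records (deduplication, derived kinematics, speed filtering),
    detects port visits robust to missing fixes, segments vessel streams
    into dock-to-dock trips, matches trips to landings records (fish
    tickets) and at-sea observer logs, computes trip durations and
    distances with port extrapolation and hub in-port constants, classifies
    trips as fishing or non-fishing with decision rules plus a logistic
    generalized additive model, and quantifies the distance underestimation
    caused by transmission gaps through a record-removal simulation. A
    synthetic-fleet generator with ground truth makes every stage testable
    without confidential data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    sp,
    mgcv,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
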