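Package: mcedcso
Title: Modeled Benefit of Cancer Signal Origin Prediction in Multi-Cancer
    Early Detection Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An interception model of multi-cancer early detection (MCED)
    screening with cancer signal origin (CSO) prediction. Converts stratified
    cancer incidence into screen-detected cancers by stage via a state-transition
    model with stage dwell times and ctDNA-shedding trajectories, assigns
    predicted CSOs to true and false positives through a pseudo-count-smoothed
    confusion model, computes the three-tier positive predictive value of the
    CSO-directed diagnostic chain, converts stage shift into expected lives saved
    and diagnostic tests per life saved, propagates posterior uncertainty in test
    performance, and compares diagnostic workup strategies. Includes a
    synthetic-data generator with known ground truth and an individual-level
    Monte-Carlo screening simulator used as a brute-force validation oracle.
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
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
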