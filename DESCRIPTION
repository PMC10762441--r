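Package: diveontogeny
Title: Dive Classification and Diving Ontogeny from Time-Depth Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and behavioural classification of time-depth recorder
    (TDR) data from diving marine mammals, oriented towards the ontogeny of
    diving in juvenile elephant seals. Provides zero-offset correction, dive
    detection and phase segmentation, bottom-phase activity metrics, rule-based
    classification of dives into active-bottom, drift, benthic and transit
    types, per-dive drift-rate (buoyancy) estimation by kernel density of
    vertical speed, daily ontogeny summaries with neutral-buoyancy crossing
    detection, solar day/night partitioning from interpolated tracks, cohort
    statistics (dive-weighted type proportions, two-sample z-test for
    proportions, Mann-Whitney U), and a synthetic trip generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
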