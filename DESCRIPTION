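Package: tonetrans
Title: Signaling-Game Transmission of an Artificial Tone System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of how an artificial melodic system,
    built on the Bohlen-Pierce scale, is learned, transmitted and
    structurally regularized in two-player signaling games, together with
    the auditory-oddball stimulus design used as an fMRI functional
    localizer and the ROI-to-ROI resting-state connectivity correlation
    stage. Provides Hamming-distance coordination, transmission and
    innovation indices, melodic Shannon entropy and interval compression
    ratios with a permutation oracle, balanced oddball event extraction,
    a synthetic cohort generator, and a Bonferroni-corrected
    neurobehavioral correlation report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    jsonlite
Config/testthat/edition: 3
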