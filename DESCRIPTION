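Package: dualforage
Title: Dual Marine-Terrestrial Foraging Analysis from GPS Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the dual (marine and terrestrial) foraging
    strategy of central-place-foraging seabirds from GPS logger data:
    foraging-trip segmentation and metrics (range, total distance,
    straightness, destination class), multi-scale First-Passage-Time
    detection of area-restricted search with variance-of-log(FPT) spectra,
    availability-versus-use terrestrial habitat selection with Monte-Carlo
    chi-squared tests, stable-isotope (delta13C/delta15N) two-endmember
    mixing regression against time spent at sea, and a seeded synthetic
    track/landscape/isotope generator with the statistical structure the
    downstream stages assume. Includes a configurable end-to-end pipeline
    with delimited-text and GeoJSON input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    mgcv,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
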