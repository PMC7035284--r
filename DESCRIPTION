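Package: handscale
Title: Data-Driven Handwriting Quality Scales from Digitizer Pen Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess children's handwriting from digitizer (tablet)
    pen recordings sampled at 60 Hz. Extracts a catalogue of 62 static,
    kinematic, pressure and pen-tilt features from stroke time series
    (including frequency-domain tremor and fluency summaries), normalizes
    feature values against age- and gender-conditional cubic norm curves to
    bounded feature scores, and builds unsupervised severity scales by
    projecting standardized deviations onto principal axes, clustering with
    K-means, and mapping the distance to the typical-writer centroid to a
    numeric handwriting score with quantile-based severity categories.
    Includes a synthetic-recording generator with planted age trends and
    deficit knobs so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
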