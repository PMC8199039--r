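Package: skiscore
Title: Motion-Quality Scoring for Alpine Skiing from Boot-Mounted Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a wearable-system processing chain for quantifying
    motion quality in alpine skiing from boot-cuff inertial measurement units
    (IMUs) and a 1 Hz GNSS speed track. Runs are segmented into turns from
    peaks in the roll-axis gyroscope signal (pendulum model of skiing),
    enriched with edge angle, edge-angle symmetry, radial force and speed,
    time-normalized to 101 points per turn, and classified by style and turn
    size. A centered principal-component reference model is learned per
    variable, style and size from a gold-standard cohort, and new turns are
    scored by absolute Z-scores of their PC projections, binned, weighted by
    explained variance and mapped to a continuous 1-10 scale. Includes seeded
    synthetic-data generators for raw sensor streams and enriched turn
    cohorts, validation statistics (Pearson correlation with effect-size
    bands, Kruskal-Wallis, skewness), and JSON persistence of fitted
    reference models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
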