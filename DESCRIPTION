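Package: migflight
Title: Nocturnal Migratory Flight Detection and Annual-Cycle Segmentation
    from Accelerometer Activity Loggers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for converting annual accelerometer-logger activity records
    of nocturnally migrating songbirds (5-minute samples scored 0-5) into
    detected night flights, migratory flight segments and cohort statistics.
    Includes run-based flight-bout detection, stopover-gap clustering of
    flight nights into autumn and spring segments, a departure-delay
    (Zugknick) rule separating the last two spring segments, odd-flight
    classification, cohort summary tables with Brown-Forsythe/Levene
    heterogeneity tests, double-plotted actogram construction and rendering,
    and a solar-geometry-constrained synthetic annual-itinerary generator
    with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    png,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
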