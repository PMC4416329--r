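Package: glyvar
Title: Glycemic Variability Metrics from Continuous Glucose Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the standard glycemic-variability parameters of a
    continuous glucose monitoring (CGM) recording: time-averaged area
    above/below an adjustable target range (Avg. AUC-H/L), percentage of
    time spent above/below the target range (PATR/PBTR), standard
    deviation, continuous overall net glycemic action (CONGA), mean of
    daily differences (MODD), and the mean amplitude of glycemic
    excursions (MAGE) via a modified Baghurst turning-point algorithm
    that retains 'W' and 'M' patterns, relocates the start point when no
    meaningful excursion is reachable from the first sample, and
    rechecks the curve before the first detected excursion. Includes
    CareLink-style and generic CSV readers, alignment of readings to a
    fixed 5-minute grid with bounded linear interpolation of missing
    samples, a seeded synthetic CGM generator with closed-form expected
    metric values for testing, and JSON/CSV report output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
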