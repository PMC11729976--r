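Package: mfmtrace
Title: Automatic Scoring and Agreement Analysis for Tablet-Administered
    Distal Motor Function Items
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the digitized distal-motor-function items of the
    Motor Function Measure (items 18, 19 and 22): a data model and file
    formats for timestamped multi-pointer touch traces with device
    calibration and on-screen support layouts; trajectory geometry and
    kinematics (angular sweep, pause detection, loop counting, region
    contact classification); rubric-based automatic 0-3 scoring with
    auditable evidence; ordinal rater-agreement statistics (quadratic
    Fleiss-Cohen weighted Cohen's kappa with asymptotic confidence
    intervals, percent agreement, Landis-Koch interpretation, Bangdiwala
    agreement charts and the B statistic); and a synthetic trace
    generator emulating subjects of graded ability for end-to-end
    validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
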