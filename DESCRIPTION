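Package: pelviscreen
Title: Accelerometer-Based Screening for High Pelvic Mobility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates sagittal pelvic tilt from static 3-axis accelerometer
    captures by gravity-vector inclinometry with most-stable-window selection,
    computes tilt change across functional positions (flexed-seated, step-up)
    relative to a standing baseline, and classifies pelvic mobility against
    the 13-degree screening threshold used in pre-operative total hip
    arthroplasty assessment. Includes Bland-Altman agreement statistics,
    diagnostic metrics from 2x2 contingency tables, correlation and
    absolute-error summaries for validating a device against a radiographic
    reference, and a ground-truthed synthetic cohort simulator so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
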