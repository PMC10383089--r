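Package: stepmax
Title: Maximum Free-Living n-Minute Step Count from Event-Based Activity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Derives free-living analogues of timed walk tests from
    event-format physical-behaviour records exported by thigh-worn activity
    monitors. Builds stepping bouts and upright containers from
    sedentary/standing/stride event streams, searches all window placements
    for the maximum n-minute step count with upright-break truncation and
    deterministic tie-breaking, and computes the derived population
    measures: wear-day validity, per-subject maxima, step accumulation
    rates, stepping-proportion availability, bout availability, and
    distribution characterisation. Includes a configurable synthetic
    behaviour-stream generator so every stage can be validated end to end
    without restricted cohort data, plus a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    e1071,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
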