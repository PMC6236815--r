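Package: artflag
Title: Quantitative Evaluation of Adaptive Radiotherapy Replan Flags
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate simple adaptive radiotherapy (ART) replan
    "flags" for head and neck cancer treatment courses. Implements the
    body-contour-change flag as a maximum axial slice-based Hausdorff
    distance with a 1.5 cm threshold, DVH-parameter extraction from dose
    grids and structure masks, course-level dose accumulation by linear
    interpolation over fractions, grading of per-fraction parameters
    against survey-derived major/minor violation criteria, truth-table
    diagnostic statistics per violation category, a random-flag
    sensitivity baseline, and a synthetic phantom cohort generator
    (weight loss, localized tumor edema with a mid-course changepoint,
    shoulder shifts) with a simple bony-frame dose engine so the full
    pipeline runs without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
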