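Package: localgaze
Title: Calibration-Free Gaze Estimation with Local-Relative Eye Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Regression-based 2D gaze estimation that works immediately,
    without a per-session calibration sequence. Eye features built from
    pupil-centre and eye-corner pixel coordinates are referenced to
    per-session local origins so that data pooled across subjects become
    comparable; a weighted quadratic least-squares model fitted to such a
    multi-subject prior is then adapted online by re-weighting confirmed
    fixations from the current user. Includes session bootstrap from an
    arbitrary initial target by numerically inverting the prior model,
    dwell-time target selection with a boundary-distance error metric, a
    synthetic cohort simulator, and an experiment harness for coordinate-
    space, prior-size and static-versus-adaptive comparisons.
License: MIT + file LICENSE
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
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
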