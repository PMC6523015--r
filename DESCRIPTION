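Package: beampathqa
Title: Beam-Path Constancy Quality Assurance for Robotic Radiosurgery
    with a Cylindrical Diode Array
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for monitoring the constancy of beam-path (robot
    pointing) accuracy of a robotic radiosurgery system using a
    cylindrical diode-array phantom.  Builds per-diode correlation
    curves of relative dose change versus phantom shift from a
    parametric small-cone dose kernel, selects one high-signal diode
    per beam, and inverts measured relative-percent-difference maps
    into per-beam position errors with placement-hypothesis and
    uncertainty-margin handling.  A delivery simulator with a stated
    noise budget replaces the physical machine so the estimator's
    sensitivity to 0.3-2.0 mm systematic drifts can be verified at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
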