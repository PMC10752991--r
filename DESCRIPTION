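Package: jfisim
Title: Reduced-Order Neuromuscular Simulation of Jersey Finger Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduced-order musculoskeletal pipeline for simulating the
    jersey finger injury mechanism: Hill-type muscle-tendon units with a
    piecewise serial-elastic tendon, planar finger chains with via-point
    muscle routing, calibration of the routing against moment-arm
    reference curves and of the tendon material parameters against
    stress-strain reference curves, a two-stage grip-and-rod-retraction
    load case, and injury scoring with avulsion-force and tendon/muscle
    strain criteria. Synthetic reference-data generators emulate the
    literature inputs so the whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
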