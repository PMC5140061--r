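Package: nutkin
Title: Growth-Driven Kinematics of Plant Nutation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inverse analysis of plant circumnutation as a
    growth-driven process. A cylindrical organ is discretized into material
    (co-moving) segments whose curvature magnitude and direction evolve under
    a differential-growth field with an optional proprioceptive
    (self-straightening) term; the 3D shape is reconstructed with a zero-twist
    (parallel-transport) frame and the apical tip is projected onto the
    horizontal plane. Inverse estimators recover the principal direction of
    differential growth, its magnitude, and the rotation period either from
    horizontal apical-tip trajectories or from full curvature fields. Preset
    oscillator programs reproduce the classical pattern zoo: circles,
    ellipses of two distinct mechanisms, growth spirals, and epi- and
    hypotrochoids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
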