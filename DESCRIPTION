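Package: quadgait
Title: Limb-Work Minimization and Footfall Phasing in Quadrupedal Walking
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the mechanical work cost of symmetrical quadrupedal
    walking with sinusoidal per-limb force profiles, reconstructs
    center-of-mass velocities from the summed limb forces, and sweeps the
    positive limb-work cost over the duty factor by limb phase plane to
    locate work-minimizing footfall phasings, including suspended
    (sloth-like) progression, fore-aft impulse bias and medial force
    variants. Also provides the observational side of the analysis:
    Hildebrand duty factor and limb phase estimated from timed footfall
    events, a packaged table of median gait parameters for 52 species,
    two-group k-means classification, phase-on-duty-factor regression, and
    a seeded synthetic footfall-event generator for estimator validation.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
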