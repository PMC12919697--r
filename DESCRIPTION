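Package: protonDMLC
Title: Dynamic Multi-Leaf Collimator Planning for Intensity-Modulated
    Proton Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale treatment-planning toolkit for proton pencil beam
    scanning (PBS) with a dynamic multi-leaf collimator (dMLC). Provides
    per-energy-layer leaf sequencing in water-equivalent beam's-eye-view
    space (a target-enclosing "cover" mode and an organ-at-risk shielding
    "block" mode), hexagonal spot placement with lateral margins, an
    aperture-aware analytic pencil-beam dose engine, worst-case robust
    spot-weight optimization over setup and range uncertainty scenarios,
    DVH/EUD plan metrics with scenario evaluation, 2D gamma-index
    verification, and a synthetic-phantom generator so the whole pipeline
    runs without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
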