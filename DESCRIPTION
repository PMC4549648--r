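Package: fretwave
Title: Sensitized-Emission FRET Ratio Imaging and Traveling-Wave Analysis for RhoGTPase Activity
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying RhoGTPase (RhoA/Cdc42) activity in
    growth cones from two-channel sensitized-emission FRET time-lapse movies:
    shading and background correction, optional photobleach correction, spectral
    bleedthrough estimation from single-fluorophore controls, donor-threshold cell
    masking, ratio-image computation, cell-edge detection and classification along
    region-of-interest scan lines, delta-F/F0 activity traces, activation-onset
    latency, and traveling-wave period estimation from maxima intervals. Includes a
    forward simulator that renders synthetic two-channel movies with prescribed edge
    motion schedules, activity hotspots, retrograde traveling waves and realistic
    acquisition nuisances (shading, background, bleedthrough, photobleaching,
    Poisson-Gaussian noise), so every stage is verifiable by parameter recovery
    without real microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
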