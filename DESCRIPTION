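Package: snarescape
Title: Quantitative Analysis of Plasma-Membrane SNARE Organization and
    Vesicle Encounters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single-molecule localization microscopy (SMLM) analysis tools
    for plasma-membrane SNARE proteins and secretory vesicles: synthetic
    ground-truth generators (clustered molecular maps, biased vesicle
    placement, localization noise and blinking, EMCCD movie rendering),
    Gaussian localization and multi-resolution rendering, probability-image
    particle detection with marker-controlled segmentation, Interacting
    Multiple Model (IMM) Kalman tracking with optimal frame-to-frame
    assignment, Ripley K/L point-pattern statistics with Monte-Carlo
    envelopes, vesicle-centric occupancy counting within the SNARE
    interaction window, track kinematics and turning-angle analysis, and a
    Brownian/Ornstein-Uhlenbeck encounter simulation integrated by
    Euler-Maruyama on a periodic domain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    minpack.lm,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
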