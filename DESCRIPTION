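Package: vesiscope
Title: Fusion-Event Detection and Myelin Sheath Dynamics from pHluorin
    Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Vesiscope", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end quantification of axonal synaptic-vesicle fusion
    imaged with pHluorin-based reporters along myelinating axons.  Detects
    focal fusion events in 2D+T fluorescence movies (bleach correction,
    rigid registration, dF/F transforms, thresholded candidate search with
    an exhaustive brute-force oracle), segments myelin sheath gaps,
    heminodes and nodes from a static axonal reporter profile, computes
    per-compartment event frequencies and the heminodal observed-versus-
    expected enrichment statistic, matches sheaths across imaging sessions
    to derive growth rates and fates, and ships a synthetic-movie generator
    with known ground truth so that every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
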