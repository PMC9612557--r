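Package: colonycapture
Title: Colony Growth, Migration and Lineage-Capture Simulation for
    Time-Lapse Microscopy Experiment Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the effective throughput of long-term
    time-lapse microscopy of motile cell colonies. Provides exact
    disk-rectangle capture geometry for a camera field of view, stochastic
    simulators of colony growth (synchronized cell cycle and
    continuous-time pure-birth models) coupled to random-walk migration,
    closed-form random-walk and first-passage analytics, a synthetic
    fluorescence-movie generator with ground-truth lineages, and a
    segmentation-and-tracking pipeline (flat-field paraboloid correction,
    threshold segmentation, optimal-assignment linking, division-calling
    heuristics) evaluated against that ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    clue,
    tiff,
    jsonlite,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
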