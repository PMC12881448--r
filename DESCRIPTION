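Package: edascope
Title: Event-Driven Hybrid Microscopy Acquisition: Simulation, Detection and Control
Version: 0.1.0
Authors@R: person("EDA", "Scope Developers", email = "edascope@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully synthetic-testable implementation of hybrid
    event-driven acquisition (hybrid-EDA) for live-cell microscopy. Provides a
    virtual phase-contrast/fluorescence microscope with scripted rare organelle
    events (mitochondrion-droplet contacts, divisions) and a light-dose
    dependent viability model; Gaussian-heatmap event detectors (single-frame,
    multi-frame channel-stacked, and stateful U-Nets with a convolutional LSTM
    memory bottleneck) trained with binary cross-entropy or soft focal loss; an
    F-beta driven evaluation kit with threshold optimization; the two-state
    surveillance/correlative acquisition controller; and downstream
    quantifications (survival curves with exponential-decay fits, duty-cycle
    arithmetic, image-quality metrics, DRP1 tip ratios, and TMRE track
    classification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
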