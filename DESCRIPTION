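Package: conflictephys
Title: Behavioral Electrophysiology Analysis for Approach-Avoidance Conflict
    Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-unit and local field potential
    recordings from rodent approach-avoidance conflict sessions. Provides
    event-aligned Z-scored peristimulus time histograms with excitatory,
    inhibitory, transient and sustained response classification; optogenetic
    photoidentification from laser-aligned millisecond histograms using a
    triangle-method latency threshold and Fano-factor reliability gate;
    pose-track detection of freezing, avoidance and risk-assessment bouts
    with behavior-aligned neural response classification; Welch power
    spectral density and band-fraction summaries of field potentials; exact
    proportion tests and behavioral principal component analysis for group
    reports; and a synthetic session generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
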