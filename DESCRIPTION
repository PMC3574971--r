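Package: wmsync
Title: Oscillatory Working-Memory Control Networks with Theta-Alpha Phase
    Locking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a star network of Wilson-Cowan excitatory-inhibitory
    units in which a Central Unit selectively phase-locks a subset of Memory
    Units, a mechanism for real-time working-memory control by partial
    synchronization. Provides fixed-step Runge-Kutta integration of the
    coupled network (compiled core), event-scripted task scenarios
    (move-a-dot, multi-task, error correction) with a coincidence-detection
    output stage, and phase analyses: peak-based instantaneous phase,
    relative phase error in cycles, lock-time detection, dominant frequency,
    attractor classification, bifurcation scans, and n:m cross-frequency
    phase-locking values.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
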