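Package: smrbci
Title: Sensorimotor-Rhythm Brain-Computer Interface Pipeline and Race Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete four-class motor/mental-imagery EEG decoding pipeline
    for cue-based brain-computer interfaces: Butterworth filtering, Laplacian
    derivations, statistical trial rejection, event-related
    (de)synchronization maps with bootstrap significance, shrinkage-regularized
    common spatial patterns, logarithmic band-power features, shrinkage linear
    discriminant analysis, cross-validated evaluation with adjusted-Wald chance
    levels, thresholded online decision making with blink and autoregressive
    artifact gating, and a pad-based racing-game simulator for closed-loop
    evaluation.  A synthetic sensorimotor-rhythm EEG generator with
    class-dependent band-power modulation over configurable scalp topographies
    makes every stage testable without recorded subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
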