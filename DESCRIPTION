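Package: sweetfuse
Title: Sweet-Period Discovery and Vision/sEMG Fusion for Grasp
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Temporal analysis of visually derived grasp classification
    during natural reach-and-grasp movements: valid-frame proportion
    curves, anchored sweet-period window discovery, plurality-vote
    confidence scoring, max-confidence fusion of egocentric-vision and
    surface-electromyography (sEMG) decision streams, and a
    leave-one-repetition-out cross-validation harness. Includes a
    calibrated synthetic decision-stream generator emulating a 30-subject
    grasp cohort (10 gestures, 18 objects, 4 repetitions) so every stage
    is testable without video data or trained classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
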