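Package: motionfuzz
Title: Fuzzy-Logic Motion Detection for a Two-Module Forearm Bracelet Sensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mamdani-style fuzzy inference for classifying forearm motions
    (wrist extension, ulnar deviation, finger flexion, wrist flexion, and the
    resting state) from a two-channel bracelet sensor voltage signal.
    Implements calibrated triangular fuzzification with 50% label overlap, a
    36-rule fuzzy rule base, weighted-centroid defuzzification, argmax
    decision with temporal tie-breaking, windowed stream classification,
    accuracy evaluation with transition margins and failure-sequence
    flagging, and a synthetic signal generator emulating per-motion plateau
    signatures. Includes a command-line interface for simulation,
    calibration, classification and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
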