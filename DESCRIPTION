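Package: cdwheat
Title: Soil-Wheat Cadmium Transfer Models and Safe-Production Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Log-linear transfer models predicting cadmium (Cd) content of
    wheat grain from soil total or bioavailable Cd and soil properties
    (pH, cation exchange capacity), with closed-form back-calculation of
    soil Cd thresholds at a grain food-safety limit, protection-accuracy
    scoring against stepwise pH-band soil quality standards, a calibrated
    synthetic soil-wheat dataset generator, and a repeated-split machine
    learning benchmark harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    rpart,
    randomForest,
    ranger,
    xgboost,
    e1071,
    caret,
    yaml,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
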