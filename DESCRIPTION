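Package: moodsense
Title: Passive Estimation of Depression Severity from Wearable and Smartphone Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for passive monitoring of depressive symptom
    severity in major depressive disorder. Reads Empatica-E4-style wrist
    biosensor exports (electrodermal activity on both wrists, 3-axis
    acceleration, inter-beat intervals, skin temperature) together with
    smartphone event logs and GPS traces; computes windowed physiological and
    behavioural features (skin conductance level and responses with bilateral
    asymmetry, time- and frequency-domain heart-rate variability, actigraphy
    sleep, screen engagement, communication, app usage, and semantic mobility);
    fits a residualized HDRS-17 regression as an averaged ensemble of gradient
    boosting and random forest over 25 reduced features; evaluates under
    user-split and time-split hold-out scenarios against naive baselines; and
    ranks features with an all-relevant Boruta selector. A synthetic-cohort
    generator with known ground-truth couplings stands in for restricted
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    signal,
    zoo,
    geosphere,
    ranger,
    xgboost,
    kernlab,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
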