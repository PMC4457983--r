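Package: adlsense
Title: Recognition of Activities of Daily Living from Ambient Home Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for recognising activities of daily living (ADL) from
    wireless ambient sensor streams recorded in private homes. Provides the
    sensor data-packet model with parity-checked serialization and
    acquisition statistics, a synthetic smart-home simulator that renders
    circadian ADL schedules into multi-channel sensor streams, stable
    bucket/radix sorting and occupancy segmentation, a rule-based
    forward-chaining inference classifier driven by a configurable
    behavioural-knowledge repository, a circadian activity rhythm classifier
    that groups recurring standardized activity patterns across days,
    Gaussian naive Bayes and random forest baseline classifiers, and
    epoch-level evaluation (sensitivity/specificity, leave-one-out
    cross-validation, activity maps).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    yaml,
    randomForest,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
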