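Package: mate
Title: Fatigue-Failure Ergonomic Risk Assessment from Musculoskeletal Model Outputs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Full-body ergonomic risk assessment engine that evaluates
    musculoskeletal-model outputs (muscle activations and joint contact
    forces) against tissue-specific fatigue-failure injury thresholds: the
    maximal acceptable effort (MAE) for functional muscle groups, the
    endurance limit of hip joint cartilage, and an age-, sex- and
    BMI-dependent vertebral fatigue-failure probability with a calibrated
    low/high-risk cutoff. Also implements the classic ergonomic scales it
    is compared against (the revised NIOSH lifting equation, RULA and
    REBA), a threshold-calibration procedure for labeled material-handling
    tasks, readers and writers for OpenSim motion-storage (STO/MOT) and
    delimited text, and a synthetic-data generator so the whole pipeline
    is testable without instrumented recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
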