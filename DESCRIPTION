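Package: msiprescreen
Title: MSI/dMMR Pre-Screening from H&E Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating an AI pre-screening (rule-out)
    pipeline for microsatellite instability (MSI) and mismatch-repair
    deficiency (dMMR) from routine H&E histology slides: slide tessellation
    into physically sized tiles, Canny-based tile quality control, Macenko
    stain normalization, pluggable tile-level scoring with a compact
    trainable backbone, patient-level score aggregation, three
    threshold-calibration strategies (cohort-specific at fixed sensitivity,
    fixed global, and learned by within-cohort cross-validation), triage
    confusion statistics with bootstrap confidence intervals, and
    leave-one-cohort-out study orchestration. Includes a synthetic-data
    module that renders two-class H&E-like textures through a Beer-Lambert
    stain model and simulates multi-cohort patient-score tables, so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
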