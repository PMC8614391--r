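Package: wearbreaks
Title: Wear-Time Validation and Structural-Break Analysis of Wearable Activity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for yearlong consumer-wearable cohorts: heart-rate-arbitrated
    wear-time validation of minute-level activity-tracker exports, construction of
    date-indexed cohort time series of steps, light physical activity,
    moderate-to-vigorous physical activity and sedentary time, detection and dating
    of multiple structural breaks in those series with BIC/RSS-optimal dynamic
    programming segmentation and moving-block bootstrap confidence intervals, and
    quantification of between-period changes with participant-level random-intercept
    mixed models and Bonferroni-adjusted pairwise contrasts. Includes a synthetic
    cohort generator with known ground truth for validation of the full chain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    lme4,
    emmeans,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
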