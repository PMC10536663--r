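Package: gaitspec
Title: Spectral Gait-Quality Indices from Wrist-Worn Accelerometer Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures gait quality from triaxial wrist-accelerometer
    recordings by discrete Fourier analysis of the acceleration magnitude.
    Provides the power-weighted mean frequency, frequency variance, and
    spectral entropy of the gait band; longitudinal tracking of the
    percentage entropy variation between the initial and final periods of a
    monitoring campaign; cohort-level summaries with a confidence interval
    for the ratio of geometric means of deterioration versus improvement;
    human-activity-recognition feature extraction over 30-second windows
    with a pluggable activity classifier; and a synthetic walk simulator
    implementing a power-conserving spectral degradation model for
    validation without raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    broom,
    caret,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
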