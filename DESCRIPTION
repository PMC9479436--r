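Package: coda24
Title: Compositional Analysis of 24-Hour Movement Behaviour Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the composition of the 24-hour day --
    sleep, sedentary time (SED), light physical activity (LPA) and
    moderate-to-vigorous physical activity (MVPA) -- changes across a life
    transition such as retirement. Implements the simplex geometry needed
    for time-use epidemiology (closure, multiplicative zero replacement,
    perturbation, compositional means, sequential-binary-partition balance
    coordinates with inverse, ternary coordinates with bootstrapped
    Mahalanobis confidence regions, and a log-contrast outlier screen),
    per-balance longitudinal linear mixed models, a synthetic cohort and
    wrist-accelerometer epoch-stream generator with known ground truth,
    and processing of epoch summaries (non-wear detection, log-guided
    sleep detection, ENMO intensity classification, bedtime-to-bedtime day
    segmentation and validity filtering) into daily compositions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
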