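Package: oculosway
Title: Concurrent Assessment of Postural Sway and Saccadic Eye Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for concurrent dual-task assessment of saccadic eye
    movements and standing balance in virtual-reality environments. Builds
    seedable stimulus schedules for eleven experimental conditions spanning
    eyes-open/closed baselines, 2D and 3D pro-/anti-saccade tasks, and
    visuospatial-memory and spatial-orientation dual tasks; simulates
    synchronized gaze, pupil, and centre-of-pressure recordings with known
    ground truth; detects saccades and scores trials (latency, peak speed,
    error rate, gaze-duration target selection); computes posturography
    metrics (COP displacement SD, mean sway speed, convex-envelope sway
    area) and a Welch pupil power-spectral-density summary; and runs a
    nonparametric statistical battery (Levene and Shapiro-Wilk checks,
    aligned-rank-transform factorial ANOVA, pairwise Wilcoxon signed-rank
    tests with effect sizes and Holm adjustment, Spearman association
    matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
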