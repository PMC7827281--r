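Package: exertrack
Title: Skeletal Exercise Assessment and Progress Analytics for Older Adults
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for supervising physical exercise with a depth-sensor
    skeletal stream: a 25-joint skeletal data model with vector and angle
    primitives, biometric calibration of limb vectors and exercise goal
    coordinates, rule-based validity assessment of concentric, squat and
    isometric scapular-retraction exercises with elderly-adapted tolerance
    margins, per-repetition range-of-motion measurement, a finite-state
    hand-swipe gesture recognizer, a seeded simulator of synthetic skeletal
    streams and multi-participant longitudinal studies, and nonparametric
    session-progress analytics (Mann-Whitney U, Wilcoxon signed-rank,
    Spearman rank correlation) with percentile-whisker boxplot summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
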