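Package: antisaccade
Title: Analysis of Interleaved Pro-/Anti-Saccade Gap-Task Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify voluntary saccade inhibition from gaze
    recordings collected in an interleaved pro-/anti-saccade gap paradigm:
    velocity-threshold saccade detection, trial scoring (correct, direction
    error, anticipatory, no response), delimitation of the express-saccade
    epoch from latency histograms by a per-bin exact binomial sign test,
    per-subject inhibition metrics (mean and coefficient of variation of
    saccadic reaction time, anti-effect, error rates by latency epoch,
    disease-burden score), and the group-level statistical battery
    (two-by-two mixed-design ANOVA with partial eta squared, two-sample
    Kolmogorov-Smirnov comparison of latency distributions, Pearson
    correlation, Shapiro-Wilk normality annotation). A synthetic gaze-trace
    and cohort generator with main-sequence kinematics provides ground truth
    so the whole pipeline runs and is testable without access to patient
    recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
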