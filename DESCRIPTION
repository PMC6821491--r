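Package: pagfear
Title: Single-Unit Analysis of Ventrolateral Periaqueductal Gray Firing
    During Pavlovian Fear Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyze single-unit spike trains recorded during
    Pavlovian fear discrimination with danger, uncertainty and safety cues.
    Implements conditioned-suppression ratios, peri-cue spike binning with
    baseline-differential Z-score normalization, screening for cue-inhibited
    neurons, k-means classification into Flip and Sustain functional
    populations, trial-by-trial encoding regression against fear-output and
    threat-probability regressors, threat-probability tuning curves, and
    shared statistics (studentized bootstrap confidence intervals, exact sign
    tests, within-subject two-factor ANOVA, Pearson correlation).  Includes a
    seeded synthetic-session generator (behavior and inhomogeneous Poisson
    spike trains with parameterized response archetypes) so every stage can
    be validated against planted ground truth, and a pipeline runner that
    produces tidy tables and a JSON summary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
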