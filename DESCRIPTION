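Package: symdynhrv
Title: Symbolic-Dynamics Heart Rate Variability Analysis for Crossover Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing cardiac autonomic modulation from
    beat-to-beat RR-interval recordings. Implements smoothness-priors
    detrending, deterministic stationary-segment selection, symbolic
    dynamics (V0/V1/V2 three-beat pattern families), JZS default
    Bayes-factor pairwise tests with Westfall-corrected prior odds,
    two-way repeated-measures ANOVA with Mauchly/Greenhouse-Geisser
    diagnostics, Tukey post-hoc contrasts, noncentral-F a priori sample
    size computation, and a seeded synthetic RR-interval / cohort
    generator emulating a three-condition caffeine supplementation
    crossover with 16 km cycling time trials.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
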