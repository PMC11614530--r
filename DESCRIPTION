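Package: ioiratio
Title: Inter-Onset-Interval Ratio Analysis of Rhythmic Behavioural Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies rhythm in annotated behavioural event sequences
    (animal vocalizations and movements) using music-derived interval
    statistics. Extracts inter-onset intervals and their pairwise ratios,
    classifies ratios into small-integer rhythm categories (isochrony 1:1,
    plus 1:3, 1:2, 2:1, 3:1) against configurable on/off-integer bins,
    estimates sequence regularity with a small-sample-corrected coefficient
    of variation, compares observed ratio distributions with a simulated
    uniform null via the two-sample Kolmogorov-Smirnov test, and fits
    mixed models for regularity and isochrony rate with colony, production
    mode and display directedness as fixed effects. Includes readers for
    Praat TextGrid and BORIS-style event logs, a synthetic-colony
    generator with known ground truth for validation, and an end-to-end
    reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    lme4,
    lmerTest,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
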