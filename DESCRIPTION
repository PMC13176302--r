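Package: circarelapse
Title: Circadian Rest-Activity Analysis of Relapse from Wrist Actigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying circadian rest-activity
    rhythms around discharge from inpatient alcohol-use-disorder treatment and
    subsequent relapse.  Reads Actiware-style one-minute epoch exports, daily
    sleep/alcohol diaries and a participant manifest; applies wear-time quality
    control (the 6-hour day rule and the 30-percent/30-day participant gate);
    computes the nonparametric circadian statistics interdaily stability (IS),
    intradaily variability (IV), M10, L5 and relative amplitude under
    sample-variance conventions; detects daily wake (activity-onset) times with
    a rank-filter/adaptive-threshold algorithm; aligns observations into
    relapse- and discharge-anchored weeks; and fits random-intercept linear and
    logistic mixed models for the effect of discharge on rhythms, of rhythms on
    relapse probability, and of relapse on rhythms.  Includes seeded epoch- and
    observation-level cohort simulators so every stage is testable without
    protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lmerTest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
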