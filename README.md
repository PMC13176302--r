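# circarelapse

Circadian rest–activity analysis of relapse risk from wrist actigraphy.

People leaving a structured inpatient alcohol-treatment setting experience an
abrupt change of zeitgebers — schedules, light, meals, supervision — and their
rest–activity rhythms reorganise accordingly. `circarelapse` is a tidyverse-style
R package for studying that transition with wrist-worn actigraphy: it reads
Actiware-style one-minute epoch exports together with daily sleep/alcohol
diaries, applies wear-time quality control, computes the nonparametric
circadian statistics, detects daily wake (activity-onset) times, aligns
observations into discharge- and relapse-anchored weeks, and fits
random-intercept mixed models for three questions:

1. how discharge changes circadian variables (linear mixed model,
   `value ~ outpatient + (1 | participant)`),
2. whether preceding circadian variables predict relapse (logistic mixed
   model, `relapse ~ value + (1 | participant)`, odds ratio `exp(β)`),
3. how relapse changes circadian variables, adjusting for discharge
   (`value ~ post_relapse + outpatient + (1 | participant)`).

## The statistics

For each participant-week (grouped by setting), with minute epochs
`X_1 … X_N`, hour-of-day means `X̄_h` (p = 24 bins) and chronological hourly
means `X̄_j` (N_h of them):

- **Interdaily stability** — day-to-day regularity of the 24-h profile,
  using sample variances (note the N−1 and p−1 denominators):

  IS = [ Σ_h (X̄_h − X̄)² / (p−1) ] / [ Σ_i (X_i − X̄)² / (N−1) ]

- **Intradaily variability** — within-day fragmentation, the mean squared
  successive difference of the hourly means over their variance:

  IV = [ Σ_j (X̄_j − X̄_{j−1})² / (N_h−1) ] / [ Σ_j (X̄_j − m)² / (N_h−1) ]

- **M10 / L5 / RA** — per day, hourly activity totals are ranked; M10 is the
  mean of the 10 largest, L5 the mean of the 5 smallest, RA = M10 − L5.

- **Wake time** — per day, the first transition out of the principal rest
  period, found by running-median smoothing, an adaptive quantile-midpoint
  threshold, and morphological cleaning of short rest/active runs.

Quality control follows strict boundaries: a day is analyzable when at most
6 h of its epochs are missing or flagged non-wear; a participant is retained
when a diary exists and not more than 30% of the first 30 recorded days are
invalid; weekly IS/IV require at least 4 valid days in the week.

Because real cohorts of this kind are available only on request, the package
ships two seeded simulators: an epoch-level generator (two-state diurnal
counts with wake-time jitter, fragmentation, non-wear gaps, discharge/relapse
regime changes, and matching diaries) and an observation-level generator that
draws metric values directly from the random-intercept models.

## Worked example

```r
library(circarelapse)

spec   <- cohort_spec(n_participants = 20, seed = 7)
cohort <- generate_cohort(spec)

qc <- apply_cohort_filters(cohort$epochs, cohort$diaries, cohort$manifest)
qc$flow
#> # A tibble: 1 × 4
#>   n_input n_excluded_no_diary n_excluded_weartime n_retained
#>     <int>               <int>               <int>      <int>
#> 1      20                   0                   0         20

assignment <- assign_relapse(cohort$diaries, cohort$manifest)
labels     <- index_weeks(qc$valid_days, assignment, cohort$manifest)
wake       <- detect_wake_times(qc$epochs, qc$valid_days)
daily      <- compute_daily_metrics(qc$epochs, qc$valid_days, wake = wake) |>
  dplyr::inner_join(labels, by = c("participant_id", "date"))
weekly     <- compute_weekly_metrics(qc$epochs, labels)

rows <- build_observation_rows(daily, weekly, assignment,
                               "wake_time", "relapse_effect")
fit <- fit_relapse_effect_lmm(rows)
tidy(fit)
#> # A tibble: 3 × 8
#>   term         estimate std.error    df statistic  p.value conf.low conf.high
#>   <chr>           <dbl>     <dbl> <int>     <dbl>    <dbl>    <dbl>     <dbl>
#> 1 (Intercept)    29776.      321.   613     92.9  0          29148.    30405.
#> 2 post_relapse    3099.      336.   613      9.22 4.56e-19    2441.     3758.
#> 3 outpatient      2732.      338.   613      8.09 3.13e-15    2070.     3394.
```

The `post_relapse` coefficient says that after the first drinking day, wake
time is about 3,100 s (~0.9 h) later than before it, over and above the
outpatient shift — recovering, within its standard error, the +3,190 s that
the simulator programmed.
`run_pipeline(run_config(...))` performs all of the above in one call and
writes every table (QC report, attrition flow, metrics, observation rows,
model estimates, diagnostics) as delimited text into a run directory.

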