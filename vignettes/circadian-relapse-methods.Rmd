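---
title: "Methods: circadian rest-activity analysis around discharge and relapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian rest-activity analysis around discharge and relapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(circarelapse)
```

## The problem this package addresses

Wrist actigraphy records gross motor activity as per-minute counts. In people
treated for alcohol use disorder, the transition from a scheduled inpatient
ward to independent outpatient life removes most external zeitgebers at the
same moment that relapse risk peaks, so the rest-activity rhythm is both a
readout of that transition and a candidate predictor of outcome.
`circarelapse` implements the full analysis chain for such a cohort: epoch
ingestion, wear-time quality control, nonparametric circadian statistics,
wake-onset detection, relapse-anchored windowing, and random-intercept mixed
models. Everything is tabular: epochs, days, weeks and model terms are rows
of tibbles, and each stage is an ordinary function from one tibble to the
next.

## Data model and conventions

Epochs are one minute long, and a "day" is the wall-clock calendar day,
half-open `[00:00, 24:00)`. Timestamps are parsed as local wall-clock time
and never shifted between timezones: wake times are reported on the clock
the participant lives by, and a daylight-saving transition simply yields a
23- or 25-hour calendar day. An epoch flagged EXCLUDED carries no usable
wear information and is dropped from every mean; an epoch absent from the
file is treated the same way at the day level.

Quality control uses strict boundaries, with equality retaining:

* a day is analyzable when **at most 360 minutes** (6 h) are missing or
  excluded — 360 passes, 361 fails;
* a participant is retained when a diary exists and **not more than 30%** of
  the first 30 recorded days are invalid — 9 of 30 passes, 10 fails.
  Records shorter than 30 days are gated on all recorded days; we count
  *recorded* days rather than elapsed calendar days, since a gap with no
  epochs at all is indistinguishable from a device left in a drawer, and
  per-participant gate inputs are written to the QC report for audit.

## The nonparametric statistics

For one participant-week within one setting, with valid minute epochs
$X_1 \dots X_N$, hour-of-day means $\bar X_h$ ($p = 24$) and chronological
hourly means $\bar X_j$ ($N_h$ of them):

$$\mathrm{IS} = \frac{\sum_{h=1}^{p}(\bar X_h - \bar X)^2/(p-1)}
                     {\sum_{i=1}^{N}(X_i - \bar X)^2/(N-1)},\qquad
  \mathrm{IV} = \frac{\sum_{j=2}^{N_h}(\bar X_j - \bar X_{j-1})^2/(N_h-1)}
                     {\sum_{j=1}^{N_h}(\bar X_j - m)^2/(N_h-1)}.$$

Both use *sample* variances (the $N-1$, $p-1$ denominators), not the
population forms of the older literature. Two consequences are useful as
checks: a perfectly daily-periodic, hour-constant signal attains
$\mathrm{IS} = (N-1)p/[(p-1)N] \approx 1.0434$ for a 7-day week (slightly
above 1), and white-noise hourly means give IV near 2. Both are asserted to
machine precision in the test suite, alongside brute-force double-loop
oracles on random data.

Numerical choices:

* an hourly mean requires at least 30 valid minutes; sparser hours are
  *absent*, and IV lag-1 pairs that span an absent hour are skipped (the
  numerator then averages over the valid pairs);
* a perfectly unfragmented signal (all successive differences zero) has
  IV = 0 even when the hourly-mean variance is also zero; any other
  zero-variance degeneracy propagates as `NA`, never as 0;
* IS is undefined (`NA`) for a constant signal — 0/0 is not a rhythm;
* the IV denominator uses the variance of the *hourly means*; the variance
  of the minute epochs is available via `denominator = "epoch"` because the
  convention differs between software packages and the two can differ
  substantially on noisy data.

M10/L5 rank the 24 hourly activity *totals* of each day and average the top
10 and bottom 5; RA is the difference M10 − L5 (not the normalised ratio
used elsewhere in the literature). Hours with some excluded minutes are
rescaled to a 60-minute equivalent (total × 60 / worn minutes) so a
half-worn hour is not artificially pushed to the bottom of the ranking; days
with fewer than 15 computable hours are skipped for these metrics.

## Wake-onset detection

The wake-time estimator is a deterministic rest/active segmentation:

1. smooth the counts with a running median of width 61 min (rank filters
   preserve edges, so a true square-wave onset is recovered exactly);
2. binarise at the midpoint of the 10% and 90% quantiles of the smoothed
   counts — a quantile-based threshold makes the estimator invariant to
   rescaling the counts;
3. morphologically clean runs: active runs shorter than 30 min become rest,
   rest runs shorter than 30 min are closed;
4. for each day, the principal rest period is the longest rest run of at
   least 120 min ending within that day; the wake time is the first epoch
   after it, in seconds after that day's midnight.

Days with no qualifying rest run, and records whose quantile spread is below
10 counts (no rest-active structure at all), yield an absent estimate with
`confidence = "low"`. On simulated two-state days (rest Poisson mean 5,
active mean 300) the mean absolute onset error is well under the 30-minute
tolerance used in the acceptance checks; parameters live in `wake_params()`
and the defaults above were fixed against synthetic data before any
downstream modelling.

One measurement property is worth knowing: the detected onset is defined
relative to the rest-activity *structure*, so interventions that change
fragmentation also shift the detected onset slightly even when the
programmed wake time is unchanged. The end-to-end recovery study therefore
isolates the wake effect (fragmentation deltas zero) and validates the
fragmentation effects separately through the calibration study.

## Windowing and model families

Weeks count backward from an anchor: for relapsers the relapse day (the
first outpatient day with any alcohol in the diary) is the first day of week
0, so week 1 is the 7 days immediately pre-relapse; for non-relapsers week 1
is the final 7 recorded days. Days after the anchor take indices 0, −1, −2,
…; a leading partial week keeps its natural index with its actual day count.
Weekly IS/IV require at least 4 valid days in the (week, setting) group, and
a week straddling discharge contributes one group per setting. Daily metrics
keep every valid day regardless.

The setting indicator is 0 up to and including the discharge date and 1
after it; the relapse-phase indicator is 1 from the relapse day onward.
Diary days absent from the file are treated as missing, not as zero drinks —
assuming abstinence on unreported days would bias relapse dates late. Heavy
drinking days use the sex-specific thresholds (≥4 drinks female, ≥5 male;
participants with unreported sex use the lower threshold, the conservative
choice). Drinking is assessed over a 28-day outpatient window.

Three model families, all with a participant random intercept fitted by
`lme4`:

* **discharge**: `value ~ outpatient + (1 | participant)`, on the subset
  with at least 4 valid inpatient days, spanning the inpatient days plus the
  first outpatient week;
* **relapse probability**: `relapsed ~ value + (1 | participant)` (logistic)
  on pre-relapse observations only;
* **relapse effect**: `value ~ post_relapse + outpatient + (1 | participant)`
  on all observations.

Reported degrees of freedom for the linear Wald tests are residual
(observations minus fixed-effect parameters); Satterthwaite df via
`lmerTest` are available with `ddf = "satterthwaite"`. Confidence intervals
are Wald, β ± 1.96·SE.

### Inference for the logistic family

The relapse outcome is constant within participant. Under a random
intercept this pushes the intercept variance toward the boundary, and the
Wald standard error of the predictor becomes unreliable: in null
simulations at the package's study conditions the Wald test rejected either
never (fast PIRLS fits) or far too often through degenerate fits (adaptive
quadrature), neither of which is a usable test. The package therefore takes
the focal p-value from the likelihood-ratio test against the intercept-only
model, which is close to nominal (empirical type-I error 0.03–0.05 at
α = 0.05 in the packaged studies), and still reports the Wald Z and
odds ratio `exp(β)` as the table statistics. Quasi-separation is detected
and flagged on the fit object rather than raised as an error.

### Group comparisons

`compare_groups()` compares relapsers with non-relapsers on each variable
using one value per participant (their study-period mean), a two-tailed
t-test, and the absolute pooled-SD standardized mean difference (Cohen's d
with unequal-n pooling). Medians and IQRs are reported alongside for
non-symmetric variables. Participant-level aggregation keeps the test's
units at the group sizes (e.g. 77 vs 26), not at the day level where
repeated measures would fake precision.

### Assumption checks

`assumption_checks()` summarises the residual-vs-fitted spread and the
normal Q-Q agreement of each linear fit. The Q-Q correlation uses
SD-standardized residuals; the tail flag compares the extreme (0.5%)
quantiles of *robustly* scaled residuals (IQR/1.349) against the normal
quantiles, because heavy tails inflate the plain SD and would otherwise hide
themselves. Limited tail deviation (ratio ≤ 1.5) is tolerated.

## The simulators

Two generators ship with the package, both fully seeded (identical spec and
seed give identical output):

**Epoch level** (`generate_cohort()`). Each participant is a two-state
diurnal process: counts are near-zero Poisson during rest and overdispersed
negative binomial during the active period (overdispersion is the norm for
activity counts), with a wake transition at a base time plus day-to-day
Gaussian jitter, an active period of fixed length, and rest intrusions
("fragmentation") arriving at a per-minute rate with geometric lengths.
Discharge applies deltas (wake shift, active-level multiplier, fragmentation
change); an optional relapse day applies further deltas; non-wear gaps are
marked EXCLUDED; diaries are generated consistently with the programmed
relapse day. Defaults are the study conditions: 103 participants, 1–7
inpatient days (about a third reaching the 4-day subset threshold), 28
outpatient days, a quarter relapsing with days-until-relapse from a gamma
with mean 10.5 and SD 6.09 truncated to 1–28, baseline wake 07:44, jitter SD
1800 s, discharge wake delta +3461 s, relapse wake delta +3190 s. Jitter
controls realized IS and fragmentation controls realized IV; the
calibration study verifies both relationships are monotone.

**Observation level** (`simulate_observations()`). Draws metric values
directly from the random-intercept model the inference stage assumes. This
is the right granularity for parameter-recovery, type-I-error and coverage
studies of the model fits: effects such as "IV decreases by exactly 0.08"
are only defined at the observation level, whereas at the epoch level a
fragmentation change maps to an IV change only through an empirical,
noisy calibration.

What the simulators do *not* emulate: light or temperature channels,
naps and shift work, weekday/weekend structure, diary misreporting, or any
dependence of relapse on prior rhythms (relapse timing is exogenous). A
pipeline that passes on these cohorts is verified for its arithmetic,
windowing, filtering and estimation logic — not for clinical validity on
free-living data.

## Sizes used by the packaged studies

The acceptance studies use 100 simulated cohorts per recovery scenario, 400
(linear) and 200 (logistic) null simulations, 3 epoch-level cohorts for the
end-to-end check, and calibration grids of five points with 8 participants ×
14 days each; within each calibration arm the grid points share one seed
(common random numbers) so the comparison isolates the parameter being
varied. These sizes put Monte-Carlo error comfortably inside the margins
being asserted while keeping a full run in the minutes range on one CPU.

## Known limitations

* The wake estimator reports one onset per day; split sleep or night work
  would need a different principal-rest definition.
* The 30%/30-day gate uses recorded days; a device never returned simply
  ends the record rather than counting against the gate.
* Logistic estimates condition on the realized relapse split; cohorts with
  very few relapsers will produce wide, flagged fits rather than errors.
* No multiplicity adjustment is applied across variables or families.
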