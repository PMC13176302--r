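#' Specification for an epoch-level synthetic cohort
#'
#' Describes a cohort whose statistical structure matches what the analysis
#' assumes: one-minute activity counts from a two-state (rest/active) diurnal
#' process with day-to-day wake-time jitter (which controls realized IS),
#' within-day fragmentation (which controls realized IV), overdispersed
#' active-period counts, an inpatient-to-outpatient regime change at
#' discharge, an optional relapse day with programmed post-relapse effects,
#' non-wear gaps, and diaries consistent with the programmed drinking.
#'
#' Defaults are the study conditions: roughly a quarter of participants
#' relapse, a median of about 11 outpatient days until relapse (gamma with
#' mean 10.5, SD 6.09 truncated to 1..28), 28 outpatient diary days, a ~07:44
#' baseline wake time, and short inpatient wear (1-7 days, about a third of
#' participants reaching the 4-day inpatient-subset threshold).
#'
#' @param n_participants Cohort size (default 103).
#' @param inpatient_days_values,inpatient_days_probs Discrete distribution of
#'   valid inpatient wear days.
#' @param outpatient_days Outpatient recording days (default 28).
#' @param relapse_fraction Probability of relapse (default 26/103).
#' @param relapse_day_mean,relapse_day_sd Gamma moments for the relapse day,
#'   truncated to `1..outpatient_days`.
#' @param rest_mean,active_mean Mean counts per minute in rest/active states.
#' @param active_size Negative-binomial size (dispersion) for active counts.
#' @param wake_base Baseline wake time, seconds after midnight (default 27840
#'   = 07:44).
#' @param wake_jitter_sd Day-to-day wake-time jitter SD in seconds.
#' @param active_hours Active-period duration in hours (default 16).
#' @param frag_rate Per-minute probability that a rest intrusion starts during
#'   the active period.
#' @param frag_mean_len Mean intrusion length in minutes.
#' @param discharge_wake_delta,relapse_wake_delta Programmed wake-time shifts
#'   (seconds) applied from discharge / from the relapse day.
#' @param discharge_active_mult Multiplier on the active-period mean after
#'   discharge (raises M10).
#' @param discharge_frag_delta,relapse_frag_delta Additive changes to
#'   `frag_rate` after discharge / relapse (negative lowers realized IV).
#' @param nonwear_rate Per-day probability of a non-wear gap.
#' @param nonwear_mean_len Mean non-wear gap length in minutes.
#' @param diary_drink_prob Probability a post-relapse day has drinking.
#' @param diary_drink_mean Mean drinks (above 1) on a drinking day.
#' @param deterministic_counts If `TRUE`, epochs carry the state means exactly
#'   (no count noise); with zero jitter and fragmentation this yields an
#'   exactly periodic profile, useful for closed-form metric checks.
#' @param seed Integer seed; identical spec + seed gives an identical cohort.
#' @return List of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_participants = 103L,
                        inpatient_days_values = 1:7,
                        inpatient_days_probs = c(0.26, 0.26, 0.13, 0.12,
                                                 0.10, 0.07, 0.06),
                        outpatient_days = 28L,
                        relapse_fraction = 26 / 103,
                        relapse_day_mean = 10.5,
                        relapse_day_sd = 6.09,
                        rest_mean = 5,
                        active_mean = 300,
                        active_size = 2,
                        wake_base = 27840,
                        wake_jitter_sd = 1800,
                        active_hours = 16,
                        frag_rate = 0.01,
                        frag_mean_len = 20,
                        discharge_wake_delta = 3461,
                        discharge_active_mult = 1.1,
                        discharge_frag_delta = -0.004,
                        relapse_wake_delta = 3190,
                        relapse_frag_delta = -0.002,
                        nonwear_rate = 0.05,
                        nonwear_mean_len = 120,
                        diary_drink_prob = 0.5,
                        diary_drink_mean = 3,
                        deterministic_counts = FALSE,
                        seed = 1L) {
  stopifnot(relapse_fraction >= 0, relapse_fraction <= 1,
            abs(sum(inpatient_days_probs) - 1) < 1e-8,
            relapse_fraction == 0 || outpatient_days >= 1)
  spec <- as.list(environment())
  structure(spec, class = "cohort_spec")
}

# truncated-gamma relapse day on 1..max_day
draw_relapse_day <- function(n, mean, sd, max_day) {
  shape <- (mean / sd)^2
  rate <- shape / mean
  d <- pmax(1L, pmin(max_day, as.integer(round(stats::rgamma(n, shape, rate)))))
  d
}

#' Generate an epoch-level synthetic cohort
#'
#' Realizes a [cohort_spec()] into Actiware-shaped epochs, diaries, a manifest
#' and a truth record holding every programmed per-participant parameter.
#' All randomness flows from the spec's single seed; participants are drawn
#' in a fixed order, so identical specs give byte-identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @param start_date Calendar date of the first recorded day for the longest
#'   inpatient stay (default `"2024-03-01"`); discharge dates are aligned so
#'   every participant shares the same discharge date.
#' @return List with `epochs`, `diaries`, `manifest`, `truth` tibbles.
#' @export
generate_cohort <- function(spec, start_date = as.Date("2024-03-01")) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_participants
  ids <- sprintf("p%03d", seq_len(n))
  inpat <- if (length(spec$inpatient_days_values) == 1L) {
    rep(spec$inpatient_days_values, n)   # sample() would misread a scalar
  } else {
    sample(spec$inpatient_days_values, n, replace = TRUE,
           prob = spec$inpatient_days_probs)
  }
  relapsed <- stats::runif(n) < spec$relapse_fraction
  relapse_day <- ifelse(
    relapsed,
    draw_relapse_day(n, spec$relapse_day_mean, spec$relapse_day_sd,
                     spec$outpatient_days),
    NA_integer_
  )
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.32, 0.68))
  discharge_date <- start_date + max(inpat) - 1L

  parts <- purrr::map(seq_len(n), function(i) {
    generate_participant(
      id = ids[i], spec = spec,
      n_inpatient = inpat[i],
      discharge_date = discharge_date,
      relapse_day = relapse_day[i],
      sex = sex[i]
    )
  })
  manifest <- tibble::tibble(
    participant_id = ids,
    discharge_date = discharge_date,
    sex = sex,
    age = round(stats::rnorm(n, 48.6, 11.3), 1)
  )
  truth <- purrr::map(parts, "truth") |> purrr::list_rbind()
  list(
    epochs = purrr::map(parts, "epochs") |> purrr::list_rbind(),
    diaries = purrr::map(parts, "diary") |> purrr::list_rbind(),
    manifest = manifest,
    truth = truth
  )
}

# one participant's epochs + diary + truth
generate_participant <- function(id, spec, n_inpatient, discharge_date,
                                 relapse_day, sex) {
  n_days <- n_inpatient + spec$outpatient_days
  first_date <- discharge_date - n_inpatient + 1L
  dates <- first_date + seq_len(n_days) - 1L
  outpatient <- dates > discharge_date
  relapse_date <- if (!is.na(relapse_day)) discharge_date + relapse_day else as.Date(NA)
  post <- if (!is.na(relapse_day)) dates >= relapse_date else rep(FALSE, n_days)

  wake_sec <- spec$wake_base +
    spec$discharge_wake_delta * outpatient +
    spec$relapse_wake_delta * post +
    stats::rnorm(n_days, 0, spec$wake_jitter_sd)
  wake_sec <- pmin(pmax(wake_sec, 4 * 3600), 12 * 3600)
  frag <- pmax(0, spec$frag_rate +
                 spec$discharge_frag_delta * outpatient +
                 spec$relapse_frag_delta * post)
  act_mean <- spec$active_mean *
    ifelse(outpatient, spec$discharge_active_mult, 1)

  total_min <- n_days * 1440L
  state <- rep(FALSE, total_min)            # FALSE = rest
  day_off <- (seq_len(n_days) - 1L) * 1440L
  act_len <- round(spec$active_hours * 60)
  for (d in seq_len(n_days)) {
    s <- day_off[d] + round(wake_sec[d] / 60) + 1L
    e <- min(s + act_len - 1L, total_min)
    state[s:e] <- TRUE
  }
  # fragmentation: rest intrusions inside the active period
  frag_min <- rep(frag, each = 1440L)
  starts <- which(state & stats::runif(total_min) < frag_min)
  if (length(starts) > 0) {
    lens <- 1L + stats::rgeom(length(starts), 1 / spec$frag_mean_len)
    idx <- unlist(purrr::map2(starts, pmin(starts + lens - 1L, total_min), seq))
    state[unique(idx)] <- FALSE
  }
  counts <- numeric(total_min)
  n_act <- sum(state)
  mu_act <- rep(act_mean, each = 1440L)[state]
  if (isTRUE(spec$deterministic_counts)) {
    counts[state] <- mu_act
    counts[!state] <- spec$rest_mean
  } else {
    counts[state] <- stats::rnbinom(n_act, size = spec$active_size, mu = mu_act)
    counts[!state] <- stats::rpois(total_min - n_act, spec$rest_mean)
  }

  excluded <- rep(FALSE, total_min)
  gap_days <- which(stats::runif(n_days) < spec$nonwear_rate)
  for (d in gap_days) {
    len <- min(1440L, 1L + stats::rgeom(1, 1 / spec$nonwear_mean_len))
    s <- day_off[d] + sample.int(1440L - len + 1L, 1)
    excluded[s:(s + len - 1L)] <- TRUE
  }

  epochs <- tibble::tibble(
    participant_id = id,
    datetime = as.POSIXct(paste(first_date, "00:00:00"), tz = "UTC") +
      60 * (seq_len(total_min) - 1L),
    date = rep(dates, each = 1440L),
    minute = rep(0:1439, n_days),
    count = counts,
    excluded = excluded
  )

  out_dates <- dates[outpatient]
  drinks <- rep(0L, length(out_dates))
  if (!is.na(relapse_day)) {
    after <- out_dates >= relapse_date
    drinking <- after & (out_dates == relapse_date |
                           stats::runif(length(out_dates)) < spec$diary_drink_prob)
    drinks[drinking] <- 1L + stats::rpois(sum(drinking), spec$diary_drink_mean)
  }
  diary <- tibble::tibble(
    participant_id = id,
    date = out_dates,
    bed_time = wake_seconds_to_clock(
      pmin(86340, wake_sec[outpatient] + spec$active_hours * 3600) %% 86400),
    wake_time = wake_seconds_to_clock(pmin(86340, wake_sec[outpatient])),
    drinks = drinks
  )
  truth <- tibble::tibble(
    participant_id = id,
    sex = sex,
    n_inpatient_days = n_inpatient,
    discharge_date = discharge_date,
    relapsed = !is.na(relapse_day),
    relapse_date = relapse_date,
    wake_base = spec$wake_base,
    discharge_wake_delta = spec$discharge_wake_delta,
    relapse_wake_delta = spec$relapse_wake_delta,
    frag_rate = spec$frag_rate,
    wake_jitter_sd = spec$wake_jitter_sd
  )
  list(epochs = epochs, diary = diary, truth = truth)
}

#' Inject non-wear missingness into an epoch series
#'
#' Marks programmed runs of epochs EXCLUDED.  With `target_day_fail`, the run
#' is placed to make exactly those calendar days fail the 6-h day rule
#' (a 361-minute run each), so QC-gate failures can be constructed
#' deterministically.
#'
#' @param epochs Epoch tibble (one participant).
#' @param runs Optional tibble `date`, `start_minute`, `length` of runs to
#'   exclude.
#' @param target_day_fail Optional vector of dates to make invalid.
#' @return The epoch tibble with updated `excluded`.
#' @export
inject_missingness <- function(epochs, runs = NULL, target_day_fail = NULL) {
  if (!is.null(target_day_fail)) {
    add <- tibble::tibble(date = as.Date(target_day_fail),
                          start_minute = 0L, length = 361L)
    runs <- dplyr::bind_rows(runs, add)
  }
  if (is.null(runs) || nrow(runs) == 0) return(epochs)
  for (i in seq_len(nrow(runs))) {
    sel <- epochs$date == runs$date[i] &
      epochs$minute >= runs$start_minute[i] &
      epochs$minute < runs$start_minute[i] + runs$length[i]
    epochs$excluded[sel] <- TRUE
  }
  epochs
}

#' Attrition-demo cohort preset
#'
#' A constructed cohort for exercising the QC gates end to end: `n_total`
#' participants of whom `n_no_diary` lack diaries and `n_gate_fail` carry
#' injected non-wear making strictly more than 30% of their recorded days
#' invalid, so [apply_cohort_filters()] retains exactly
#' `n_total - n_no_diary - n_gate_fail`.  Defaults reproduce a 126 to 103
#' attrition flow (5 diaryless, 18 wear-time failures).
#'
#' @param n_total,n_no_diary,n_gate_fail Cohort construction counts.
#' @param n_days Recorded days per participant (default 14; the gate then
#'   inspects all 14, and 5 invalid days > 30%).
#' @param seed Seed.
#' @return List `epochs`, `diaries`, `manifest` (+ `expected_flow`).
#' @export
attrition_preset <- function(n_total = 126L, n_no_diary = 5L,
                             n_gate_fail = 18L, n_days = 14L, seed = 7L) {
  stopifnot(n_no_diary + n_gate_fail <= n_total)
  spec <- cohort_spec(
    n_participants = n_total,
    inpatient_days_values = 2L, inpatient_days_probs = 1,
    outpatient_days = n_days - 2L,
    relapse_fraction = 0.25,
    nonwear_rate = 0,   # all missingness injected deliberately below
    seed = seed
  )
  cohort <- generate_cohort(spec)
  ids <- unique(cohort$manifest$participant_id)
  no_diary_ids <- ids[seq_len(n_no_diary)]
  gate_ids <- ids[n_no_diary + seq_len(n_gate_fail)]
  n_fail_days <- floor(0.3 * n_days) + 1L   # strictly > 30% of recorded days
  cohort$epochs <- cohort$epochs |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(pe, key) {
      if (key$participant_id %in% gate_ids) {
        fail_dates <- sort(unique(pe$date))[seq_len(n_fail_days)]
        pe <- inject_missingness(pe, target_day_fail = fail_dates)
      }
      pe
    }) |>
    dplyr::ungroup() |>
    dplyr::select("participant_id", dplyr::everything())
  cohort$diaries <- cohort$diaries |>
    dplyr::filter(!.data$participant_id %in% no_diary_ids)
  cohort$expected_flow <- tibble::tibble(
    n_input = n_total, n_excluded_no_diary = n_no_diary,
    n_excluded_weartime = n_gate_fail,
    n_retained = n_total - n_no_diary - n_gate_fail
  )
  cohort
}

#' Observation-level simulator for the mixed-model families
#'
#' Draws circadian observations directly from the random-intercept data
#' model the inference stage assumes:
#' `value = intercept + effect_outpatient * outpatient +
#'  effect_post_relapse * post_relapse + u_participant + noise`, with
#' `u ~ N(0, sd_participant)` and `noise ~ N(0, sd_resid)`.  Used for
#' parameter-recovery, type-I-error and CI-coverage studies of the model
#' fits at arbitrary programmed effect sizes; the epoch-level generator
#' ([generate_cohort()]) exercises the same recovery through the full
#' pipeline.
#'
#' @param n_participants Number of participants.
#' @param n_inpatient_units,n_outpatient_units Observation units (days or
#'   weeks) per participant in each setting.
#' @param relapse_fraction Fraction of relapsers (their post-relapse units
#'   are the second half of their outpatient units).
#' @param intercept,effect_outpatient,effect_post_relapse Fixed effects in
#'   response units.
#' @param sd_participant,sd_resid Random-intercept and residual SDs.
#' @param seed Optional seed.
#' @return Observation-row tibble (`participant_id`, `unit`, `outpatient`,
#'   `post_relapse`, `value`, `relapsed`).
#' @export
simulate_observations <- function(n_participants,
                                  n_inpatient_units = 0L,
                                  n_outpatient_units = 28L,
                                  relapse_fraction = 0,
                                  intercept = 0,
                                  effect_outpatient = 0,
                                  effect_post_relapse = 0,
                                  sd_participant = 1,
                                  sd_resid = 1,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("s%03d", seq_len(n_participants))
  relapsed <- stats::runif(n_participants) < relapse_fraction
  u <- stats::rnorm(n_participants, 0, sd_participant)
  purrr::map(seq_len(n_participants), function(i) {
    n_units <- n_inpatient_units + n_outpatient_units
    outp <- rep(c(0L, 1L), c(n_inpatient_units, n_outpatient_units))
    post <- rep(0L, n_units)
    if (relapsed[i] && n_outpatient_units >= 2) {
      # relapse midway through the outpatient span
      start_post <- n_inpatient_units + ceiling(n_outpatient_units / 2)
      post[seq(start_post, n_units)] <- 1L
    }
    tibble::tibble(
      participant_id = ids[i],
      unit = seq_len(n_units),
      outpatient = outp,
      post_relapse = post,
      value = intercept + effect_outpatient * outp +
        effect_post_relapse * post + u[i] +
        stats::rnorm(n_units, 0, sd_resid),
      relapsed = relapsed[i]
    )
  }) |>
    purrr::list_rbind()
}
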