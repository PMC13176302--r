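#' Hourly summaries for a group of analyzable days
#'
#' IS and IV operate on hourly aggregates of the one-minute epochs, computed
#' within a grouping unit (here: one participant-week within one setting).
#' Excluded epochs are dropped from every mean; an hour with fewer than
#' `min_valid_min` worn minutes is treated as absent rather than averaged from
#' a sliver of data.
#'
#' @param epochs Valid-day epochs of one grouping unit (single participant).
#' @param min_valid_min Minimum worn minutes for an hourly mean (default 30).
#' @return List with
#'   \describe{
#'     \item{hourly}{tibble `date`, `hour`, `n_valid`, `mean` — per-calendar-hour
#'       means in chronological order, absent hours removed}
#'     \item{hour_of_day_means}{named numeric, one mean per populated hour label
#'       0-23, pooling all valid epochs sharing that label across the group's days}
#'     \item{overall_mean}{mean of all valid epochs}
#'     \item{n_epochs}{number of valid epochs}
#'     \item{epoch_counts}{the valid epoch counts themselves (IS denominator)}
#'   }
#' @export
hourly_summaries <- function(epochs, min_valid_min = 30L) {
  ok <- epochs[!epochs$excluded, ]
  if (nrow(ok) == 0) stop("no valid epochs in group", call. = FALSE)
  ok$hour <- hour_of_minute(ok$minute)
  hourly <- ok |>
    dplyr::group_by(.data$date, .data$hour) |>
    dplyr::summarise(n_valid = dplyr::n(), mean = mean(.data$count),
                     .groups = "drop") |>
    dplyr::filter(.data$n_valid >= min_valid_min) |>
    dplyr::arrange(.data$date, .data$hour)
  hod <- ok |>
    dplyr::group_by(.data$hour) |>
    dplyr::summarise(mean = mean(.data$count), .groups = "drop")
  list(
    hourly = hourly,
    hour_of_day_means = stats::setNames(hod$mean, hod$hour),
    overall_mean = mean(ok$count),
    n_epochs = nrow(ok),
    epoch_counts = ok$count
  )
}

#' Interdaily stability (IS)
#'
#' Variance-ratio statistic for the day-to-day consistency of the 24-h
#' activity profile: the sample variance of the 24 hour-of-day means divided
#' by the sample variance of the individual one-minute epochs,
#' \deqn{IS = \frac{\sum_h (\bar X_h - \bar X)^2 / (p-1)}
#'                 {\sum_i (X_i - \bar X)^2 / (N-1)}}
#' with p = 24 hour bins and N valid epochs.  Sample (N-1, p-1) variances are
#' used throughout, not the population forms.  Higher IS means a more regular
#' daily rhythm; a perfectly repeating daily profile attains the maximum
#' (N-1)p / ((p-1)N).
#'
#' @param h Output of [hourly_summaries()] for one week-setting group.
#' @return IS as a non-negative scalar, or `NA_real_` when undefined (fewer
#'   than 2 epochs or populated hour labels, or zero epoch variance).
#' @export
interdaily_stability <- function(h) {
  xh <- h$hour_of_day_means
  p <- length(xh)
  if (h$n_epochs < 2 || p < 2) return(NA_real_)
  denom <- stats::var(h$epoch_counts)        # sample variance, N-1
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  num <- sum((xh - h$overall_mean)^2) / (p - 1)
  num / denom
}

#' Intradaily variability (IV)
#'
#' Fragmentation statistic: the mean squared successive difference of the
#' chronological hourly means divided by their variance,
#' \deqn{IV = \frac{\sum_{j=2}^{N_h} (\bar X_j - \bar X_{j-1})^2 / (N_h - 1)}
#'                 {\sum_{j=1}^{N_h} (\bar X_j - m)^2 / (N_h - 1)}}
#' with \eqn{N_h} hourly means and m their mean.  Lag-1 pairs that span an
#' absent hour (a gap in the worn record) are skipped, and the numerator then
#' averages over the valid pairs.  White-noise hourly means give IV near 2;
#' a smooth diurnal profile gives values well below 1.
#'
#' @param h Output of [hourly_summaries()].
#' @param denominator `"hourly"` (default) uses the sample variance of the
#'   hourly means; `"epoch"` uses the sample variance of the one-minute
#'   epochs instead.
#' @return IV as a non-negative scalar, or `NA_real_` when undefined (fewer
#'   than 3 hourly means, no valid lag pairs, or zero variance).
#' @export
intradaily_variability <- function(h, denominator = c("hourly", "epoch")) {
  denominator <- match.arg(denominator)
  hh <- h$hourly
  n_h <- nrow(hh)
  if (n_h < 3) return(NA_real_)
  # consecutive = successive rows exactly one clock hour apart
  t_index <- as.numeric(hh$date) * 24 + hh$hour
  consec <- diff(t_index) == 1
  d <- diff(hh$mean)[consec]
  if (length(d) == 0) return(NA_real_)
  num <- sum(d^2) / length(d)
  # perfectly non-fragmented signal: IV is 0 even when the variance is 0 too
  if (num == 0) return(0)
  denom <- if (denominator == "hourly") stats::var(hh$mean) else stats::var(h$epoch_counts)
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  num / denom
}

#' Daily M10, L5 and relative amplitude
#'
#' For one valid day, hourly total activity counts are ranked; M10 is the mean
#' of the 10 largest hourly totals, L5 the mean of the 5 smallest, and the
#' relative amplitude RA = M10 - L5 (a difference, not a normalised ratio).
#' Hours with some excluded minutes are rescaled to a 60-minute equivalent
#' (total x 60 / worn minutes) so partial hours do not sink artificially in
#' the ranking; hours with fewer than `min_valid_min` worn minutes are not
#' computable.  Days with fewer than `min_hours` computable hours are skipped.
#'
#' @param day_epochs Epoch tibble for a single participant-day.
#' @param min_hours Minimum computable hours (default 15).
#' @param min_valid_min Minimum worn minutes per computable hour (default 30).
#' @return One-row tibble `m10`, `l5`, `ra`, `n_hours`; all-`NA` metrics when
#'   the day is skipped.
#' @export
daily_m10_l5_ra <- function(day_epochs, min_hours = 15L, min_valid_min = 30L) {
  ok <- day_epochs[!day_epochs$excluded, ]
  totals <- ok |>
    dplyr::mutate(hour = hour_of_minute(.data$minute)) |>
    dplyr::group_by(.data$hour) |>
    dplyr::summarise(n_valid = dplyr::n(), total = sum(.data$count),
                     .groups = "drop") |>
    dplyr::filter(.data$n_valid >= min_valid_min) |>
    dplyr::mutate(total = .data$total * 60 / .data$n_valid)
  if (nrow(totals) < min_hours) {
    return(tibble::tibble(m10 = NA_real_, l5 = NA_real_, ra = NA_real_,
                          n_hours = nrow(totals)))
  }
  t_sorted <- sort(totals$total, decreasing = TRUE)
  m10 <- mean(t_sorted[1:10])
  l5 <- mean(utils::tail(t_sorted, 5))
  tibble::tibble(m10 = m10, l5 = l5, ra = m10 - l5, n_hours = nrow(totals))
}

#' Per-day circadian metrics for a cohort
#'
#' Computes M10/L5/RA for every valid day, optionally merging wake-time
#' estimates from [detect_wake_times()].
#'
#' @param epochs Retained epoch tibble.
#' @param valid_days [day_validity()] table; only `valid` days are used.
#' @param wake Optional wake-estimate tibble (`participant_id`, `date`,
#'   `wake_time`).
#' @inheritParams daily_m10_l5_ra
#' @return Tibble `participant_id`, `date`, `m10`, `l5`, `ra`, `n_hours`
#'   (+ `wake_time` when supplied).
#' @export
compute_daily_metrics <- function(epochs, valid_days, wake = NULL,
                                  min_hours = 15L, min_valid_min = 30L) {
  keep <- valid_days[valid_days$valid, c("participant_id", "date")]
  out <- epochs |>
    dplyr::inner_join(keep, by = c("participant_id", "date")) |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::group_modify(~ daily_m10_l5_ra(.x, min_hours = min_hours,
                                          min_valid_min = min_valid_min)) |>
    dplyr::ungroup()
  if (!is.null(wake)) {
    out <- dplyr::left_join(out, wake[, c("participant_id", "date", "wake_time")],
                            by = c("participant_id", "date"))
  }
  out
}

#' Per-week IS and IV for a cohort
#'
#' Groups valid days by (participant, relative week, setting) and computes IS
#' and IV for every group with at least `min_days` valid days; a week
#' straddling discharge contributes one group per setting.
#'
#' @param epochs Retained epoch tibble.
#' @param day_labels Day-label tibble from [index_weeks()] (columns
#'   `participant_id`, `date`, `week_index`, `setting`; only valid days).
#' @param min_days Minimum valid days per week-setting group (default 4).
#' @param iv_denominator Passed to [intradaily_variability()].
#' @return Tibble `participant_id`, `week_index`, `setting`, `is`, `iv`,
#'   `n_valid_days`.
#' @export
compute_weekly_metrics <- function(epochs, day_labels, min_days = 4L,
                                   iv_denominator = "hourly") {
  groups <- day_labels |>
    dplyr::count(.data$participant_id, .data$week_index, .data$setting,
                 name = "n_valid_days") |>
    dplyr::filter(.data$n_valid_days >= min_days)
  if (nrow(groups) == 0) {
    return(tibble::tibble(participant_id = character(), week_index = integer(),
                          setting = character(), is = numeric(), iv = numeric(),
                          n_valid_days = integer()))
  }
  labeled <- epochs |>
    dplyr::inner_join(
      day_labels[, c("participant_id", "date", "week_index", "setting")],
      by = c("participant_id", "date")
    )
  labeled |>
    dplyr::inner_join(groups, by = c("participant_id", "week_index", "setting")) |>
    dplyr::group_by(.data$participant_id, .data$week_index, .data$setting,
                    .data$n_valid_days) |>
    dplyr::group_modify(function(gdf, key) {
      h <- hourly_summaries(gdf)
      tibble::tibble(
        is = interdaily_stability(h),
        iv = intradaily_variability(h, denominator = iv_denominator)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select("participant_id", "week_index", "setting", "is", "iv",
                  "n_valid_days")
}
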