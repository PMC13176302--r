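#' Wake-detection settings
#'
#' Parameters of the activity-onset detector: a running-median (rank) filter,
#' an adaptive threshold placed midway between a low and a high quantile of
#' the smoothed counts, and morphological cleaning of implausibly short rest
#' or active runs.  All widths/runs are in minutes.
#'
#' @param filter_width Odd running-median window (default 61 min).
#' @param threshold_quantiles Two probabilities; the threshold is the midpoint
#'   of the corresponding quantiles of the smoothed counts (default 0.1, 0.9).
#' @param min_active_run Active runs shorter than this are relabelled rest
#'   (default 30 min).
#' @param min_rest_gap Rest runs shorter than this inside the active period
#'   are closed (default 30 min).
#' @param min_rest_run Minimum length of a principal rest period
#'   (default 120 min).
#' @param min_contrast Minimum high-low quantile spread (in counts) for a day
#'   to be considered to have rest-active structure (default 10).
#' @return List of class `"wake_params"`.
#' @export
wake_params <- function(filter_width = 61L,
                        threshold_quantiles = c(0.1, 0.9),
                        min_active_run = 30L,
                        min_rest_gap = 30L,
                        min_rest_run = 120L,
                        min_contrast = 10) {
  stopifnot(filter_width %% 2 == 1, length(threshold_quantiles) == 2)
  structure(
    list(filter_width = as.integer(filter_width),
         threshold_quantiles = threshold_quantiles,
         min_active_run = as.integer(min_active_run),
         min_rest_gap = as.integer(min_rest_gap),
         min_rest_run = as.integer(min_rest_run),
         min_contrast = min_contrast),
    class = "wake_params"
  )
}

# relabel runs of `value` shorter than min_len to !value
clean_short_runs <- function(state, value, min_len) {
  r <- rle(state)
  flip <- r$values == value & r$lengths < min_len
  r$values[flip] <- !value
  inverse.rle(r)
}

#' Detect daily wake (activity-onset) times
#'
#' Estimates, for each valid day, the wall-clock time of the transition from
#' the day's principal rest period into sustained activity.  The counts are
#' smoothed with a running median, binarised at an adaptive quantile-midpoint
#' threshold (scale-invariant by construction), cleaned morphologically, and
#' the wake time is the first epoch after the longest qualifying rest run
#' ending within the day.  Deterministic for fixed parameters.  Excluded
#' epochs are bridged by linear interpolation before smoothing.
#'
#' @param epochs Epoch tibble (one or more participants).
#' @param valid_days [day_validity()] table; estimates are produced for valid
#'   days only.
#' @param params A [wake_params()] object.
#' @return Tibble `participant_id`, `date`, `wake_time` (seconds after that
#'   day's midnight, `NA` when no rest period is detectable), `confidence`
#'   (`"ok"` or `"low"`).
#' @export
detect_wake_times <- function(epochs, valid_days = day_validity(epochs),
                              params = wake_params()) {
  validate_epochs(epochs)
  epochs |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(pe, key) {
      vd <- valid_days$date[valid_days$participant_id == key$participant_id &
                              valid_days$valid]
      detect_wake_one(pe, vd, params)
    }) |>
    dplyr::ungroup()
}

# one participant's full record -> per-valid-day estimates
detect_wake_one <- function(pe, valid_dates, params) {
  empty <- tibble::tibble(date = as.Date(character()),
                          wake_time = numeric(), confidence = character())
  if (length(valid_dates) == 0 || nrow(pe) == 0) return(empty)
  pe <- pe[order(pe$datetime), ]
  x <- pe$count
  x[pe$excluded] <- NA_real_
  x <- fill_na_linear(x)
  sm <- stats::runmed(x, params$filter_width, endrule = "median")
  qs <- stats::quantile(sm, params$threshold_quantiles, names = FALSE)
  if (diff(qs) < params$min_contrast) {
    # flat record: no rest-active structure anywhere
    return(tibble::tibble(date = valid_dates, wake_time = NA_real_,
                          confidence = "low"))
  }
  thr <- mean(qs)
  active <- sm >= thr
  active <- clean_short_runs(active, TRUE, params$min_active_run)
  active <- clean_short_runs(active, FALSE, params$min_rest_gap)
  # rest runs as index ranges
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rest <- !r$values & r$lengths >= params$min_rest_run
  rest_runs <- tibble::tibble(start = starts[rest], end = ends[rest],
                              len = r$lengths[rest])
  purrr::map(valid_dates, function(d) {
    day_idx <- which(pe$date == d)
    if (length(day_idx) == 0) {
      return(tibble::tibble(date = d, wake_time = NA_real_, confidence = "low"))
    }
    lo <- min(day_idx); hi <- max(day_idx)
    # candidate principal rest periods: end within this day, successor exists
    cand <- rest_runs[rest_runs$end >= lo & rest_runs$end < hi, ]
    if (nrow(cand) == 0) {
      return(tibble::tibble(date = d, wake_time = NA_real_, confidence = "low"))
    }
    main <- cand[which.max(cand$len), ]
    wake_idx <- main$end + 1L
    wake_sec <- pe$minute[wake_idx] * 60
    tibble::tibble(date = d, wake_time = as.numeric(wake_sec), confidence = "ok")
  }) |>
    purrr::list_rbind()
}

# linear interpolation over interior NAs, nearest value at the edges
fill_na_linear <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  if (length(idx) == 0) return(rep(0, length(x)))
  stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}

#' Render wake seconds as a 24-h clock string
#'
#' @param wake_time Seconds after midnight, in `[0, 86400)`.
#' @return Zero-padded `"HH:MM"`; seconds are truncated, not rounded.
#' @export
#' @examples
#' wake_seconds_to_clock(27840) # "07:44"
wake_seconds_to_clock <- function(wake_time) {
  if (any(wake_time < 0 | wake_time >= 86400, na.rm = TRUE)) {
    stop("wake_time out of range [0, 86400)", call. = FALSE)
  }
  sprintf("%02d:%02d", wake_time %/% 3600, (wake_time %% 3600) %/% 60)
}
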