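#' Build an epoch-series tibble
#'
#' The package represents actigraphy as a long tibble of one-minute epochs,
#' one row per epoch, chronologically ordered within participant.  All
#' downstream stages (QC, circadian metrics, wake detection) consume this
#' shape.
#'
#' @param participant_id Character scalar identifying the wearer.
#' @param start Calendar datetime (`POSIXct`, or anything `as.POSIXct()`
#'   accepts) of the first epoch.  Interpreted as local wall-clock time and
#'   stored timezone-naive (UTC internally), because circadian endpoints such
#'   as wake time are reported on the wall clock.
#' @param counts Numeric vector of non-negative activity counts, one per
#'   one-minute epoch.
#' @param excluded Logical vector parallel to `counts`; `TRUE` marks an epoch
#'   flagged as non-wear (EXCLUDED).  Recycled from a scalar.
#'
#' @return A tibble with columns `participant_id`, `datetime` (POSIXct, UTC),
#'   `date` (Date), `minute` (integer minute of day, 0-1439), `count`,
#'   `excluded`.
#' @export
#' @examples
#' es <- epoch_series("p01", "2024-03-01 00:00:00", counts = rpois(1440, 50))
#' dplyr::count(es, date)
epoch_series <- function(participant_id, start, counts, excluded = FALSE) {
  stopifnot(length(participant_id) == 1L, length(counts) >= 1L)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("activity counts must be non-negative and non-missing", call. = FALSE)
  }
  excluded <- rep_len(as.logical(excluded), length(counts))
  start <- as.POSIXct(start, tz = "UTC")
  datetime <- start + 60 * (seq_along(counts) - 1L)
  tibble::tibble(
    participant_id = as.character(participant_id),
    datetime = datetime,
    date = as.Date(datetime, tz = "UTC"),
    minute = as.integer(format(datetime, "%H", tz = "UTC")) * 60L +
      as.integer(format(datetime, "%M", tz = "UTC")),
    count = as.numeric(counts),
    excluded = excluded
  )
}

#' Validate an epoch-series tibble
#'
#' Checks the structural invariants that every pipeline stage relies on:
#' required columns, non-negative counts, and strictly increasing epoch
#' timestamps (no duplicates, no reordering) within each participant.
#'
#' @param epochs An epoch tibble as returned by [epoch_series()] or
#'   [read_epoch_file()]; may hold several participants.
#' @return `epochs`, invisibly, if valid; otherwise an error.
#' @export
validate_epochs <- function(epochs) {
  need <- c("participant_id", "datetime", "date", "minute", "count", "excluded")
  missing_cols <- setdiff(need, names(epochs))
  if (length(missing_cols) > 0) {
    stop("epoch table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(epochs$count < 0, na.rm = TRUE)) {
    stop("negative activity counts present", call. = FALSE)
  }
  bad <- epochs |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      ok = all(diff(as.numeric(.data$datetime)) > 0),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop("non-chronological or duplicate epochs for participant(s): ",
         paste(bad$participant_id, collapse = ", "), call. = FALSE)
  }
  invisible(epochs)
}

# minute-of-day (0..1439) -> hour label 0..23
hour_of_minute <- function(minute) minute %/% 60L
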