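#' Per-day wear validity
#'
#' A calendar day (midnight-to-midnight, wall clock) is analyzable when at
#' most 6 h of its one-minute epochs are missing.  "Missing" counts both
#' epochs flagged EXCLUDED (non-wear) and epochs absent from the record, so a
#' partial first or last day is penalised for the minutes never recorded.
#' The boundary is strict: exactly 360 missing minutes is still valid, 361 is
#' not.
#'
#' @param epochs Epoch tibble (one or more participants).
#' @param max_missing_min Day-level missingness bound in minutes (default 360
#'   = 6 h).
#' @return Tibble with one row per (participant, calendar day):
#'   `participant_id`, `date`, `missing_minutes`, `valid`.
#' @export
day_validity <- function(epochs, max_missing_min = 360L) {
  if (nrow(epochs) == 0) {
    warning("empty epoch series: no days to assess")
    return(tibble::tibble(participant_id = character(), date = as.Date(character()),
                          missing_minutes = integer(), valid = logical()))
  }
  epochs |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(worn = sum(!.data$excluded), .groups = "drop") |>
    dplyr::mutate(
      missing_minutes = 1440L - as.integer(.data$worn),
      valid = .data$missing_minutes <= max_missing_min
    ) |>
    dplyr::select("participant_id", "date", "missing_minutes", "valid")
}

#' Participant-level wear gate
#'
#' A participant is retained when (a) a diary exists and (b) within the first
#' 30 recorded days, not more than 30% of days are invalid under the 6-h rule.
#' Equality retains (exactly 30% passes); strictly more than 30% excludes.
#' Records shorter than 30 days are gated on all recorded days.
#'
#' @param epochs Epoch tibble for one participant.
#' @param has_diary Logical: does a diary exist for this participant?
#' @param first_days Number of leading recorded days the gate inspects
#'   (default 30).
#' @param max_invalid_frac Largest tolerated invalid-day fraction (default 0.3).
#' @inheritParams day_validity
#' @return One-row tibble: `participant_id`, `retained`, `reason`
#'   (`"ok"`, `"no_diary"`, `"wear_time"`, `"no_data"`), `n_days_gated`,
#'   `n_invalid`.
#' @export
participant_wear_gate <- function(epochs, has_diary,
                                  first_days = 30L,
                                  max_invalid_frac = 0.3,
                                  max_missing_min = 360L) {
  pid <- unique(epochs$participant_id)
  stopifnot(length(pid) <= 1)
  if (nrow(epochs) == 0 || length(pid) == 0) {
    return(tibble::tibble(participant_id = if (length(pid)) pid else NA_character_,
                          retained = FALSE, reason = "no_data",
                          n_days_gated = 0L, n_invalid = 0L))
  }
  if (!isTRUE(has_diary)) {
    return(tibble::tibble(participant_id = pid, retained = FALSE,
                          reason = "no_diary", n_days_gated = 0L, n_invalid = 0L))
  }
  dv <- day_validity(epochs, max_missing_min = max_missing_min)
  dv <- dv[order(dv$date), ]
  dv <- utils::head(dv, first_days)
  n_invalid <- sum(!dv$valid)
  fail <- n_invalid / nrow(dv) > max_invalid_frac
  tibble::tibble(
    participant_id = pid,
    retained = !fail,
    reason = if (fail) "wear_time" else "ok",
    n_days_gated = nrow(dv),
    n_invalid = as.integer(n_invalid)
  )
}

#' Apply the cohort-level QC filters
#'
#' Runs the diary and wear-time gates over a whole cohort and assembles the
#' attrition accounting.  The retained epoch set keeps all epochs of retained
#' participants; the `valid_days` table says which calendar days enter any
#' analysis.
#'
#' @param epochs Epoch tibble for the full cohort.
#' @param diaries Diary tibble ([read_diaries()] shape).
#' @param manifest Manifest tibble ([read_manifest()] shape); defines the
#'   participant universe (participants with no epochs at all still count as
#'   wear-time exclusions).
#' @inheritParams participant_wear_gate
#' @return List with elements
#'   \describe{
#'     \item{epochs}{epochs of retained participants}
#'     \item{valid_days}{[day_validity()] table for retained participants}
#'     \item{flow}{one-row tibble `n_input`, `n_excluded_no_diary`,
#'       `n_excluded_weartime`, `n_retained`}
#'     \item{report}{per-participant gate outcome with reason codes}
#'   }
#' @export
apply_cohort_filters <- function(epochs, diaries, manifest,
                                 first_days = 30L,
                                 max_invalid_frac = 0.3,
                                 max_missing_min = 360L) {
  stopifnot(nrow(manifest) > 0)
  diary_ids <- unique(diaries$participant_id)
  split_epochs <- split(epochs, epochs$participant_id)
  report <- purrr::map(manifest$participant_id, function(pid) {
    pe <- split_epochs[[pid]]
    if (is.null(pe)) pe <- epochs[0, ]
    g <- participant_wear_gate(
      pe, has_diary = pid %in% diary_ids,
      first_days = first_days, max_invalid_frac = max_invalid_frac,
      max_missing_min = max_missing_min
    )
    g$participant_id <- pid
    # a record with no epochs is a wear-time failure, not a diary one
    if (g$reason == "no_data" && pid %in% diary_ids) g$reason <- "wear_time"
    g
  }) |>
    purrr::list_rbind()
  flow <- tibble::tibble(
    n_input = nrow(manifest),
    n_excluded_no_diary = sum(report$reason == "no_diary"),
    n_excluded_weartime = sum(report$reason %in% c("wear_time", "no_data")),
    n_retained = sum(report$retained)
  )
  stopifnot(flow$n_retained ==
              flow$n_input - flow$n_excluded_no_diary - flow$n_excluded_weartime)
  kept <- report$participant_id[report$retained]
  kept_epochs <- epochs[epochs$participant_id %in% kept, ]
  list(
    epochs = kept_epochs,
    valid_days = day_validity(kept_epochs, max_missing_min = max_missing_min),
    flow = flow,
    report = report
  )
}
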