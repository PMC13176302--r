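#' Relapse assignment from the outpatient drinking diary
#'
#' Any alcohol recorded in the diary during the outpatient follow-up window
#' places the participant in the relapse group; the relapse day is the first
#' such day.  Diary days absent from the file are treated as missing (not as
#' zero drinks).  Heavy-drinking days use the sex-specific thresholds: four or
#' more drinks for females, five or more for males (participants with sex not
#' reported use the female threshold, the conservative choice).
#'
#' @param diaries Diary tibble for the cohort.
#' @param manifest Manifest tibble (needs `participant_id`, `discharge_date`,
#'   `sex`).
#' @param followup_days Length of the outpatient diary window in days
#'   (default 28); outpatient day k is `discharge_date + k`, k = 1..28.
#' @return Tibble, one row per manifest participant: `participant_id`,
#'   `relapsed`, `relapse_date`, `days_until_relapse`, `total_drinks`,
#'   `heavy_drinking_days`.
#' @export
assign_relapse <- function(diaries, manifest, followup_days = 28L) {
  no_diary <- setdiff(manifest$participant_id, unique(diaries$participant_id))
  if (length(no_diary) > 0) {
    stop("no diary for participant(s): ", paste(no_diary, collapse = ", "),
         " (exclude them upstream)", call. = FALSE)
  }
  d <- diaries |>
    dplyr::inner_join(
      manifest[, c("participant_id", "discharge_date", "sex")],
      by = "participant_id"
    ) |>
    dplyr::mutate(out_day = as.integer(.data$date - .data$discharge_date)) |>
    dplyr::filter(.data$out_day >= 1, .data$out_day <= followup_days)
  summ <- d |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      relapsed = any(.data$drinks > 0),
      relapse_date = if (any(.data$drinks > 0))
        min(.data$date[.data$drinks > 0]) else as.Date(NA),
      total_drinks = sum(.data$drinks),
      heavy_drinking_days = sum(
        .data$drinks >= ifelse(.data$sex == "male", 5L, 4L)
      ),
      .groups = "drop"
    )
  manifest |>
    dplyr::select("participant_id", "discharge_date") |>
    dplyr::left_join(summ, by = "participant_id") |>
    dplyr::mutate(
      relapsed = dplyr::coalesce(.data$relapsed, FALSE),
      total_drinks = as.integer(dplyr::coalesce(.data$total_drinks, 0L)),
      heavy_drinking_days = as.integer(dplyr::coalesce(.data$heavy_drinking_days, 0L)),
      days_until_relapse = as.integer(.data$relapse_date - .data$discharge_date)
    ) |>
    dplyr::select("participant_id", "relapsed", "relapse_date",
                  "days_until_relapse", "total_drinks", "heavy_drinking_days")
}

#' Label valid days with relative week, setting and relapse phase
#'
#' Weeks count backward from the anchor: for relapsers the relapse day is the
#' first day of week 0 (so week 1 spans the 7 days immediately pre-relapse);
#' for non-relapsers week 1 spans the final 7 recorded days.  Days after the
#' anchor take week 0, -1, -2, ...; a leading partial week simply receives the
#' next integer index with its actual day count.  The setting is inpatient up
#' to and including the discharge date and outpatient after it; the relapse
#' phase is `post` from the relapse day onward and `pre` before it (always
#' `none` for non-relapsers).
#'
#' @param valid_days [day_validity()] table (only valid rows are labeled).
#' @param assignment [assign_relapse()] table.
#' @param manifest Manifest tibble (for discharge dates).
#' @return Tibble `participant_id`, `date`, `week_index`, `setting`
#'   (`"inpatient"`/`"outpatient"`), `relapse_phase` (`"pre"`/`"post"`/`"none"`).
#' @export
index_weeks <- function(valid_days, assignment, manifest) {
  vd <- valid_days[valid_days$valid, c("participant_id", "date")]
  info <- assignment |>
    dplyr::left_join(manifest[, c("participant_id", "discharge_date")],
                     by = "participant_id")
  last_dates <- vd |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(last_date = max(.data$date), .groups = "drop")
  lab <- vd |>
    dplyr::inner_join(info, by = "participant_id") |>
    dplyr::inner_join(last_dates, by = "participant_id")
  bad <- lab |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      impossible = any(.data$relapsed) && min(.data$date) > .data$relapse_date[1],
      .groups = "drop"
    ) |>
    dplyr::filter(.data$impossible)
  if (nrow(bad) > 0) {
    stop("relapse precedes all actigraphy for: ",
         paste(bad$participant_id, collapse = ", "), call. = FALSE)
  }
  lab |>
    dplyr::mutate(
      anchor = dplyr::if_else(.data$relapsed, .data$relapse_date,
                              .data$last_date + 1L),
      days_before = as.integer(.data$anchor - .data$date),
      week_index = dplyr::if_else(
        .data$days_before >= 1L,
        (.data$days_before - 1L) %/% 7L + 1L,
        -((-.data$days_before) %/% 7L)
      ),
      setting = dplyr::if_else(.data$date > .data$discharge_date,
                               "outpatient", "inpatient"),
      relapse_phase = dplyr::case_when(
        !.data$relapsed ~ "none",
        .data$date >= .data$relapse_date ~ "post",
        TRUE ~ "pre"
      )
    ) |>
    dplyr::select("participant_id", "date", "week_index", "setting",
                  "relapse_phase")
}

#' Inpatient (pre/post-discharge) analysis subset
#'
#' Participants with at least `min_inpatient_days` valid inpatient days form
#' the discharge-effect analysis set; their contribution is the valid
#' inpatient days plus the first outpatient week (discharge + 1 .. + 7).
#'
#' @param day_labels [index_weeks()] output.
#' @param manifest Manifest tibble.
#' @param min_inpatient_days Minimum valid inpatient days (default 4).
#' @return List: `participants` (character vector) and `day_labels` (the
#'   subset's labeled days restricted to the analysis span).
#' @export
inpatient_subset <- function(day_labels, manifest, min_inpatient_days = 4L) {
  n_inp <- day_labels |>
    dplyr::filter(.data$setting == "inpatient") |>
    dplyr::count(.data$participant_id)
  ids <- n_inp$participant_id[n_inp$n >= min_inpatient_days]
  sub <- day_labels |>
    dplyr::filter(.data$participant_id %in% ids) |>
    dplyr::left_join(manifest[, c("participant_id", "discharge_date")],
                     by = "participant_id") |>
    dplyr::filter(.data$setting == "inpatient" |
                    .data$date <= .data$discharge_date + 7L) |>
    dplyr::select(-"discharge_date")
  list(participants = ids, day_labels = sub)
}

#' Build model-ready observation rows
#'
#' Emits the long-format rows each mixed-model family consumes, with the
#' indicator coding used throughout: `outpatient` 0/1 (inpatient = 0) and
#' `post_relapse` 0/1 (pre-relapse = 0; the relapse day itself is post).
#' Weekly variables (`is`, `iv`) give one row per (participant, week,
#' setting); daily variables (`m10`, `l5`, `ra`, `wake_time`) one row per
#' valid day.
#'
#' Families:
#' \describe{
#'   \item{`"discharge"`}{all supplied rows, response vs `outpatient`; pass
#'     metrics already restricted to the [inpatient_subset()] span}
#'   \item{`"relapse_prob"`}{pre-relapse rows only (relapsers truncated the
#'     day before relapse; non-relapsers contribute everything), plus the
#'     participant-level `relapsed` outcome}
#'   \item{`"relapse_effect"`}{all rows with both indicators}
#' }
#'
#' @param daily [compute_daily_metrics()] output joined with day labels
#'   (i.e. containing `week_index`, `setting`, `relapse_phase`).
#' @param weekly [compute_weekly_metrics()] output.
#' @param assignment [assign_relapse()] table.
#' @param variable One of `"is"`, `"iv"`, `"m10"`, `"l5"`, `"ra"`,
#'   `"wake_time"`.
#' @param family One of `"discharge"`, `"relapse_prob"`, `"relapse_effect"`.
#' @return Tibble `participant_id`, `unit` (date or week index), `outpatient`,
#'   `post_relapse`, `value` (+ `relapsed` for `"relapse_prob"`).
#' @export
build_observation_rows <- function(daily, weekly, assignment,
                                   variable = c("is", "iv", "m10", "l5", "ra",
                                                "wake_time"),
                                   family = c("discharge", "relapse_prob",
                                              "relapse_effect")) {
  variable <- match.arg(variable)
  family <- match.arg(family)
  if (variable %in% c("is", "iv")) {
    rows <- weekly |>
      dplyr::mutate(
        unit = .data$week_index,
        outpatient = as.integer(.data$setting == "outpatient"),
        # weekly grain: the relapse week (0) and later are post for relapsers
        post_relapse = as.integer(
          .data$participant_id %in%
            assignment$participant_id[assignment$relapsed] &
            .data$week_index <= 0L
        ),
        value = .data[[variable]]
      )
  } else {
    rows <- daily |>
      dplyr::mutate(
        unit = .data$date,
        outpatient = as.integer(.data$setting == "outpatient"),
        post_relapse = as.integer(.data$relapse_phase == "post"),
        value = .data[[variable]]
      )
  }
  rows <- rows |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::select("participant_id", "unit", "outpatient", "post_relapse",
                  "value")
  if (family == "relapse_prob") {
    rows <- rows |>
      dplyr::filter(.data$post_relapse == 0L) |>
      dplyr::inner_join(assignment[, c("participant_id", "relapsed")],
                        by = "participant_id")
  }
  rows
}
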