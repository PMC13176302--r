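#' Describe an Actiware-style export dialect
#'
#' Actiwatch exports are delimited text whose exact schema varies with the
#' software version and export options.  A dialect records the pieces the
#' reader needs: the delimiter, the number of leading lines to skip before the
#' header, and which columns carry the timestamp, the activity count and the
#' exclusion flag.
#'
#' @param sep Field delimiter (default `","`).
#' @param skip Number of lines before the header row (default 0).
#' @param date_col,time_col Column names holding the calendar date and the
#'   clock time of each epoch.
#' @param date_format,time_format `strptime()` formats for those columns.
#' @param activity_col Column holding the per-epoch activity count.
#' @param excluded_col Column holding the exclusion flag; values in
#'   `excluded_true` mark the epoch EXCLUDED (non-wear).
#' @param excluded_true Character values interpreted as "excluded".
#'
#' @return A list of class `"actiware_dialect"`.
#' @export
actiware_dialect <- function(sep = ",",
                             skip = 0L,
                             date_col = "Date",
                             time_col = "Time",
                             date_format = "%Y-%m-%d",
                             time_format = "%H:%M:%S",
                             activity_col = "Activity",
                             excluded_col = "Excluded",
                             excluded_true = c("1", "TRUE", "EXCLUDED")) {
  structure(
    list(sep = sep, skip = skip, date_col = date_col, time_col = time_col,
         date_format = date_format, time_format = time_format,
         activity_col = activity_col, excluded_col = excluded_col,
         excluded_true = excluded_true),
    class = "actiware_dialect"
  )
}

#' Read a one-participant Actiware-style epoch export
#'
#' Parses a delimited epoch file into the package's epoch tibble.  Rows
#' flagged excluded in the file come back with `excluded = TRUE`; malformed
#' rows (unparseable timestamp or count) are an error, never silently dropped,
#' and timestamps must be strictly increasing.
#'
#' @param path Path to the delimited file.
#' @param participant_id Identifier to attach; defaults to the file name
#'   without extension.
#' @param dialect An [actiware_dialect()] describing the export schema.
#'
#' @return An epoch tibble (see [epoch_series()]).
#' @export
read_epoch_file <- function(path, participant_id = NULL,
                            dialect = actiware_dialect()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- readr::read_delim(
    path, delim = dialect$sep, skip = dialect$skip,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  need <- c(dialect$date_col, dialect$time_col, dialect$activity_col,
            dialect$excluded_col)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("epoch file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) stop("epoch file ", path, " has no data rows", call. = FALSE)

  dt <- as.POSIXct(
    paste(raw[[dialect$date_col]], raw[[dialect$time_col]]),
    format = paste(dialect$date_format, dialect$time_format),
    tz = "UTC"
  )
  counts <- suppressWarnings(as.numeric(raw[[dialect$activity_col]]))
  bad <- which(is.na(dt) | is.na(counts) | counts < 0)
  if (length(bad) > 0) {
    stop("malformed epoch row(s) in ", path, " (first at data row ", bad[1], ")",
         call. = FALSE)
  }
  steps <- diff(as.numeric(dt))
  if (any(steps <= 0)) {
    stop("non-monotonic timestamps in ", path, " (first at data row ",
         which(steps <= 0)[1] + 1L, ")", call. = FALSE)
  }
  tibble::tibble(
    participant_id = as.character(participant_id),
    datetime = dt,
    date = as.Date(dt, tz = "UTC"),
    minute = as.integer(format(dt, "%H", tz = "UTC")) * 60L +
      as.integer(format(dt, "%M", tz = "UTC")),
    count = counts,
    excluded = raw[[dialect$excluded_col]] %in% dialect$excluded_true
  )
}

#' Write one participant's epochs as an Actiware-style file
#'
#' Deterministic inverse of [read_epoch_file()] under the same dialect:
#' counts, flags and timestamps round-trip bit-identically.
#'
#' @param epochs Epoch tibble for a single participant.
#' @param path Output path.
#' @inheritParams read_epoch_file
#' @return `path`, invisibly.
#' @export
write_epoch_file <- function(epochs, path, dialect = actiware_dialect()) {
  validate_epochs(epochs)
  if (nrow(epochs) == 0) stop("refusing to write an empty epoch series", call. = FALSE)
  if (dplyr::n_distinct(epochs$participant_id) != 1) {
    stop("write_epoch_file() takes a single participant", call. = FALSE)
  }
  out <- tibble::tibble(
    format(epochs$datetime, dialect$date_format, tz = "UTC"),
    format(epochs$datetime, dialect$time_format, tz = "UTC"),
    # counts are integers in real exports but kept numeric here
    epochs$count,
    as.integer(epochs$excluded)
  )
  names(out) <- c(dialect$date_col, dialect$time_col,
                  dialect$activity_col, dialect$excluded_col)
  readr::write_delim(out, path, delim = dialect$sep)
  invisible(path)
}

#' Read daily sleep/alcohol diaries
#'
#' One row per participant-day with the self-reported bed time, wake time and
#' the number of standard drinks consumed that day.  Days absent from the file
#' are treated as missing diary entries downstream (not as zero drinks).
#'
#' @param path Delimited file with columns `participant_id`, `date`,
#'   `bed_time`, `wake_time` (clock strings, may be empty), `drinks`.
#' @return Tibble with those columns, `date` as `Date`, `drinks` as integer.
#' @export
read_diaries <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    date = readr::col_date(),
    bed_time = readr::col_character(),
    wake_time = readr::col_character(),
    drinks = readr::col_integer()
  ), progress = FALSE, show_col_types = FALSE)
  if (any(is.na(d$drinks) | d$drinks < 0)) {
    stop("diary has missing or negative drink counts", call. = FALSE)
  }
  dup <- d |>
    dplyr::count(.data$participant_id, .data$date) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate diary rows for ", dup$participant_id[1], " on ",
         dup$date[1], call. = FALSE)
  }
  d
}

#' Read the participant manifest
#'
#' Participant-level record: discharge date, sex (drives the heavy-drinking
#' threshold), and any opaque covariates (age, clinical scores) carried along
#' untouched.
#'
#' @param path Delimited file with at least `participant_id`,
#'   `discharge_date`, `sex`; extra columns are kept as covariates.
#' @return Tibble, `discharge_date` as `Date`, `sex` one of
#'   `"female"`, `"male"`, `"not reported"`.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    discharge_date = readr::col_date(),
    sex = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE, show_col_types = FALSE)
  if (any(is.na(m$discharge_date))) {
    stop("manifest: discharge_date required for every participant", call. = FALSE)
  }
  bad <- setdiff(unique(m$sex), c("female", "male", "not reported"))
  if (length(bad) > 0) {
    stop("manifest: unknown sex value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Write diaries / manifest (deterministic CSV)
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
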