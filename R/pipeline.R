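#' Build a run configuration
#'
#' Collects every tunable of a pipeline run.  Defaults reproduce the
#' analysis thresholds: the 30% / 30-day participant gate, the 6-h day rule,
#' the 4-valid-days weekly rule, and the 28-day outpatient follow-up.
#'
#' @param simulate A [cohort_spec()] to generate inputs, or `NULL` to read
#'   them from `input_dir`.
#' @param input_dir Directory holding `epochs_<id>.csv`, `diaries.csv`,
#'   `manifest.csv` when `simulate` is `NULL`.
#' @param output_dir Run directory to create.
#' @param max_invalid_frac,first_days,max_missing_min QC thresholds.
#' @param min_week_days Minimum valid days for weekly IS/IV.
#' @param min_inpatient_days Inpatient-subset threshold.
#' @param followup_days Outpatient diary window.
#' @param iv_denominator `"hourly"` or `"epoch"`.
#' @param wake [wake_params()].
#' @param variables Circadian variables to model.
#' @param families Model families to fit.
#' @param seed Seed recorded (and used when simulating).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(simulate = cohort_spec(),
                       input_dir = NULL,
                       output_dir = tempfile("circarelapse_run_"),
                       max_invalid_frac = 0.3,
                       first_days = 30L,
                       max_missing_min = 360L,
                       min_week_days = 4L,
                       min_inpatient_days = 4L,
                       followup_days = 28L,
                       iv_denominator = "hourly",
                       wake = wake_params(),
                       variables = c("is", "iv", "m10", "l5", "ra", "wake_time"),
                       families = c("discharge", "relapse_prob", "relapse_effect"),
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline
#'
#' Executes simulate/load, QC, circadian metrics, wake detection,
#' relapse-aligned windowing and the requested mixed-model families, writing
#' every table produced (attrition flow, QC report, daily and weekly metrics,
#' observation rows, model estimates, diagnostics) as delimited text into the
#' run directory, together with the serialized configuration and a plain-text
#' summary.  Identical configuration and seed give identical outputs.
#'
#' @param config A [run_config()].
#' @return The run directory path, invisibly; the parsed results are attached
#'   as the attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$output_dir, name)
  cfg <- config
  cfg$simulate <- if (is.null(cfg$simulate)) NULL else unclass(cfg$simulate)
  cfg$wake <- unclass(cfg$wake)
  yaml::write_yaml(purrr::discard(cfg, is.null), out("config.yaml"))

  if (!is.null(config$simulate)) {
    cohort <- generate_cohort(config$simulate)
  } else {
    stopifnot(!is.null(config$input_dir))
    files <- list.files(config$input_dir, pattern = "^epochs_.*\\.csv$",
                        full.names = TRUE)
    cohort <- list(
      epochs = purrr::map(files, read_epoch_file) |> purrr::list_rbind(),
      diaries = read_diaries(file.path(config$input_dir, "diaries.csv")),
      manifest = read_manifest(file.path(config$input_dir, "manifest.csv"))
    )
  }

  qc <- apply_cohort_filters(
    cohort$epochs, cohort$diaries, cohort$manifest,
    first_days = config$first_days,
    max_invalid_frac = config$max_invalid_frac,
    max_missing_min = config$max_missing_min
  )
  write_table(qc$flow, out("cohort_flow.csv"))
  write_table(qc$report, out("qc_report.csv"))

  manifest <- cohort$manifest |>
    dplyr::filter(.data$participant_id %in% unique(qc$epochs$participant_id))
  assignment <- assign_relapse(
    cohort$diaries |>
      dplyr::filter(.data$participant_id %in% manifest$participant_id),
    manifest, followup_days = config$followup_days
  )
  write_table(assignment, out("relapse_assignment.csv"))

  labels <- index_weeks(qc$valid_days, assignment, manifest)
  wake <- detect_wake_times(qc$epochs, qc$valid_days, config$wake)
  daily <- compute_daily_metrics(qc$epochs, qc$valid_days, wake = wake) |>
    dplyr::inner_join(labels, by = c("participant_id", "date"))
  weekly <- compute_weekly_metrics(qc$epochs, labels,
                                   min_days = config$min_week_days,
                                   iv_denominator = config$iv_denominator)
  write_table(daily, out("daily_metrics.csv"))
  write_table(weekly, out("weekly_metrics.csv"))

  sub <- inpatient_subset(labels, manifest,
                          min_inpatient_days = config$min_inpatient_days)
  sub_daily <- dplyr::semi_join(daily, sub$day_labels,
                                by = c("participant_id", "date"))
  sub_weekly <- compute_weekly_metrics(qc$epochs, sub$day_labels,
                                       min_days = config$min_week_days,
                                       iv_denominator = config$iv_denominator)

  fits <- list()
  estimates <- purrr::map(config$families, function(fam) {
    purrr::map(config$variables, function(v) {
      rows <- switch(
        fam,
        discharge = build_observation_rows(sub_daily, sub_weekly, assignment,
                                           v, "discharge"),
        relapse_prob = build_observation_rows(daily, weekly, assignment,
                                              v, "relapse_prob"),
        relapse_effect = build_observation_rows(daily, weekly, assignment,
                                                v, "relapse_effect")
      )
      write_table(rows, out(sprintf("obs_%s_%s.csv", fam, v)))
      fit <- tryCatch(
        switch(fam,
               discharge = fit_discharge_lmm(rows),
               relapse_prob = fit_relapse_logistic(rows),
               relapse_effect = fit_relapse_effect_lmm(rows)),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        return(tibble::tibble(family = fam, variable = v,
                              error = conditionMessage(fit)))
      }
      fits[[paste(fam, v, sep = "_")]] <<- fit
      effect_estimate(fit) |>
        dplyr::mutate(family = fam, variable = v, .before = 1)
    }) |>
      purrr::list_rbind()
  }) |>
    purrr::list_rbind()
  write_table(estimates, out("model_estimates.csv"))

  comparison <- compare_groups(daily, weekly, assignment,
                               variables = config$variables)
  write_table(comparison, out("group_comparison.csv"))

  diagnostics <- purrr::imap(fits, function(f, nm) {
    if (f$family == "relapse_prob") return(NULL)
    assumption_checks(f) |> dplyr::mutate(model = nm, .before = 1)
  }) |>
    purrr::compact() |>
    purrr::list_rbind()
  write_table(diagnostics, out("diagnostics.csv"))

  summary_lines <- c(
    "circarelapse pipeline run",
    sprintf("seed: %s", config$seed),
    sprintf("cohort flow: %d input / %d no-diary / %d wear-time / %d retained",
            qc$flow$n_input, qc$flow$n_excluded_no_diary,
            qc$flow$n_excluded_weartime, qc$flow$n_retained),
    sprintf("relapsers: %d of %d", sum(assignment$relapsed), nrow(assignment)),
    sprintf("inpatient subset: %d participants", length(sub$participants)),
    sprintf("model estimates written: %d rows", nrow(estimates))
  )
  writeLines(summary_lines, out("summary.txt"))

  res <- list(qc = qc, assignment = assignment, labels = labels,
              daily = daily, weekly = weekly, estimates = estimates,
              comparison = comparison, diagnostics = diagnostics,
              fits = fits, inpatient_subset = sub)
  invisible(structure(config$output_dir, results = res))
}
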