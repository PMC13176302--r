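#' Diagnostic plot for a circadian mixed-model fit
#'
#' Residuals-versus-fitted and normal Q-Q panels for the linear families,
#' the standard visual checks applied before trusting the Wald tests.
#'
#' @param object A `"circadian_fit"` object (linear family).
#' @param ... Unused.
#' @return A ggplot object (two facets).
#' @method autoplot circadian_fit
#' @export
autoplot.circadian_fit <- function(object, ...) {
  r <- stats::residuals(object$model)
  f <- stats::fitted(object$model)
  z <- (r - mean(r)) / stats::sd(r)
  n <- length(z)
  d <- dplyr::bind_rows(
    tibble::tibble(panel = "residuals vs fitted", x = f, y = r),
    tibble::tibble(panel = "normal Q-Q",
                   x = stats::qnorm(stats::ppoints(n)), y = sort(z))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(
      data = tibble::tibble(panel = "residuals vs fitted", yint = 0),
      ggplot2::aes(yintercept = .data$yint), linetype = 2
    ) +
    ggplot2::geom_abline(
      data = tibble::tibble(panel = "normal Q-Q", sl = 1, ic = 0),
      ggplot2::aes(slope = .data$sl, intercept = .data$ic), linetype = 2
    ) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("model diagnostics:", object$family)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot daily circadian metrics aligned to discharge
#'
#' Per-participant traces of one daily variable against study day relative
#' to discharge, with setting means overlaid — the standard way to eyeball a
#' discharge regime change before modelling it.
#'
#' @param daily Labeled daily metrics (with `setting`).
#' @param manifest Manifest (for discharge dates).
#' @param variable Daily variable to plot (default `"wake_time"`).
#' @return A ggplot object.
#' @export
plot_daily_metrics <- function(daily, manifest, variable = "wake_time") {
  d <- daily |>
    dplyr::left_join(manifest[, c("participant_id", "discharge_date")],
                     by = "participant_id") |>
    dplyr::mutate(rel_day = as.integer(.data$date - .data$discharge_date),
                  value = .data[[variable]]) |>
    dplyr::filter(!is.na(.data$value))
  means <- d |>
    dplyr::group_by(.data$setting) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rel_day, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant_id),
                       alpha = 0.25, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 3) +
    ggplot2::geom_hline(data = means,
                        ggplot2::aes(yintercept = .data$value,
                                     colour = .data$setting),
                        linetype = 2) +
    ggplot2::labs(x = "day relative to discharge", y = variable,
                  colour = "setting") +
    ggplot2::theme_minimal()
}

#' Plot weekly IS/IV by weeks until relapse or study end
#'
#' @param weekly Weekly metrics.
#' @param variable `"is"` or `"iv"`.
#' @return A ggplot object.
#' @export
plot_weekly_metrics <- function(weekly, variable = "iv") {
  d <- weekly |>
    dplyr::mutate(value = .data[[variable]]) |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(d, ggplot2::aes(x = -.data$week_index, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant_id),
                       alpha = 0.25, colour = "grey40") +
    ggplot2::stat_summary(fun = mean, geom = "line", linewidth = 1) +
    ggplot2::labs(x = "weeks until relapse / study end (0 = anchor)",
                  y = toupper(variable)) +
    ggplot2::theme_minimal()
}
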