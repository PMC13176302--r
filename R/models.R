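#' Mixed-model fits for the three analysis families
#'
#' All three families are random-intercept models fitted with \pkg{lme4}:
#' a participant-level intercept absorbs within-person correlation of the
#' repeated circadian measurements, and the reported test on the focal fixed
#' effect is a Wald test.  Reported degrees of freedom are residual
#' (observations minus fixed-effect parameters); Satterthwaite df via
#' \pkg{lmerTest} are available with `ddf = "satterthwaite"`.
#'
#' @name circadian_fits
NULL

new_circadian_fit <- function(model, family, focal_term, rows, converged,
                              flags = character()) {
  structure(
    list(model = model, family = family, focal_term = focal_term,
         n_obs = nrow(rows), n_participants = dplyr::n_distinct(rows$participant_id),
         converged = converged, flags = flags),
    class = "circadian_fit"
  )
}

fit_lmm_guarded <- function(formula, rows, family, focal_term,
                            ddf = c("residual", "satterthwaite")) {
  ddf <- match.arg(ddf)
  if (stats::var(rows$value) == 0) {
    stop("degenerate fit: response is constant", call. = FALSE)
  }
  fitter <- if (ddf == "satterthwaite" &&
                requireNamespace("lmerTest", quietly = TRUE)) {
    lmerTest::lmer
  } else {
    lme4::lmer
  }
  flags <- character()
  model <- withCallingHandlers(
    fitter(formula, data = rows, REML = TRUE),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      flags <<- c(flags, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    }
  )
  converged <- length(model@optinfo$conv$lme4$messages %||% character()) == 0
  f <- new_circadian_fit(model, family, focal_term, rows,
                         converged = converged, flags = flags)
  f$ddf <- ddf
  f
}

#' Effect of discharge on a circadian variable
#'
#' Fits `value ~ outpatient + (1 | participant_id)` on the inpatient-subset
#' observation rows: the fixed `outpatient` coefficient is the mean shift in
#' the response (in its own units) on moving from the inpatient to the
#' outpatient setting.
#'
#' @param rows Observation rows from [build_observation_rows()] with family
#'   `"discharge"` (columns `participant_id`, `outpatient`, `value`).
#' @param ddf `"residual"` (default) or `"satterthwaite"`.
#' @return A `"circadian_fit"` object; see [tidy.circadian_fit()].
#' @export
fit_discharge_lmm <- function(rows, ddf = "residual") {
  if (dplyr::n_distinct(rows$outpatient) < 2) {
    stop("both settings must be represented", call. = FALSE)
  }
  if (dplyr::n_distinct(rows$participant_id) < 2) {
    stop("need at least 2 participants", call. = FALSE)
  }
  fit_lmm_guarded(value ~ outpatient + (1 | participant_id), rows,
                  family = "discharge", focal_term = "outpatient", ddf = ddf)
}

#' Effect of a circadian variable on relapse probability
#'
#' Fits the logistic mixed model
#' `relapsed ~ value + (1 | participant_id)` on pre-relapse observation rows,
#' and reports the odds ratio `exp(beta)` of relapsing per unit of the
#' circadian variable.  Quasi-separation (a predictor that perfectly splits
#' the outcomes) is flagged, not fatal.
#'
#' Because the outcome is constant within participant, the random-intercept
#' likelihood is maximised toward the boundary and Wald standard errors for
#' the predictor are unreliable (conservative or wildly anti-conservative
#' depending on where the optimizer stops).  The focal p-value is therefore
#' taken from the likelihood-ratio test against the intercept-only null
#' model; the Wald Z is still reported as the test statistic.
#'
#' @param rows Observation rows from [build_observation_rows()] with family
#'   `"relapse_prob"` (columns `participant_id`, `value`, `relapsed`).
#' @param nAGQ Integration setting for [lme4::glmer()]; 0 (default) uses the
#'   fast PIRLS approximation, 1 adaptive Gauss-Hermite.
#' @return A `"circadian_fit"` object.
#' @export
fit_relapse_logistic <- function(rows, nAGQ = 0L) {
  if (dplyr::n_distinct(rows$relapsed) < 2) {
    stop("both relapse outcomes must be present", call. = FALSE)
  }
  flags <- character()
  model <- withCallingHandlers(
    lme4::glmer(relapsed ~ value + (1 | participant_id), data = rows,
                family = stats::binomial(), nAGQ = nAGQ),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      flags <<- c(flags, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    }
  )
  co <- summary(model)$coefficients
  if (abs(co["value", "Estimate"]) > 15 / max(stats::sd(rows$value), 1e-12) ||
      co["value", "Std. Error"] > 1e3 * abs(co["value", "Estimate"]) + 1e6) {
    flags <- c(flags, "possible outcome separation")
  }
  converged <- length(model@optinfo$conv$lme4$messages %||% character()) == 0
  null_model <- suppressWarnings(suppressMessages(
    lme4::glmer(relapsed ~ 1 + (1 | participant_id), data = rows,
                family = stats::binomial(), nAGQ = nAGQ)
  ))
  lrt <- suppressWarnings(suppressMessages(stats::anova(model, null_model)))
  f <- new_circadian_fit(model, "relapse_prob", "value", rows,
                         converged = converged, flags = flags)
  f$lrt_p <- lrt$`Pr(>Chisq)`[2]
  f
}

#' Effect of relapse on a circadian variable, adjusted for discharge
#'
#' Fits `value ~ post_relapse + outpatient + (1 | participant_id)` on the full
#' observation rows (pre- and post-relapse; non-relapsers contribute
#' throughout with `post_relapse = 0`).  The focal coefficient is
#' `post_relapse`.
#'
#' @param rows Observation rows from [build_observation_rows()] with family
#'   `"relapse_effect"`.
#' @inheritParams fit_discharge_lmm
#' @return A `"circadian_fit"` object.
#' @export
fit_relapse_effect_lmm <- function(rows, ddf = "residual") {
  if (dplyr::n_distinct(rows$post_relapse) < 2) {
    stop("both relapse phases must be present", call. = FALSE)
  }
  fit_lmm_guarded(value ~ post_relapse + outpatient + (1 | participant_id),
                  rows, family = "relapse_effect", focal_term = "post_relapse",
                  ddf = ddf)
}

#' @export
print.circadian_fit <- function(x, ...) {
  cat("<circadian_fit> family:", x$family,
      "| n_obs:", x$n_obs, "| participants:", x$n_participants,
      if (!x$converged) "| NOT CONVERGED" else "", "\n")
  print(tidy(x), ...)
  invisible(x)
}

#' Extract the focal effect estimate
#'
#' Convenience wrapper returning the one-row [tidy.circadian_fit()] record
#' for the fit's focal term (the discharge, predictor, or relapse
#' coefficient).
#'
#' @param fit A `"circadian_fit"` object.
#' @return One-row tibble.
#' @export
effect_estimate <- function(fit) {
  dplyr::filter(tidy(fit), .data$term == fit$focal_term)
}

#' Model assumption diagnostics
#'
#' Summaries of the checks applied to every linear mixed fit: the spread of
#' residuals against fitted values, and the agreement of the residual
#' distribution with normal quantiles.  The Q-Q correlation is the Pearson
#' correlation of the sorted standardized residuals with the corresponding
#' normal quantiles; limited tail deviation is tolerated, but when the
#' observed extreme quantiles exceed the normal ones by more than
#' `tail_ratio_bound` the `tails_flagged` flag is raised.
#'
#' @param fit A `"circadian_fit"` from a linear family.
#' @param tail_ratio_bound Flag threshold on the observed/theoretical extreme
#'   quantile ratio (default 1.5).
#' @return Tibble with `qq_correlation`, `tail_ratio`, `tails_flagged`,
#'   `resid_fitted_cor` (correlation of absolute residuals with fitted
#'   values, a funnel-shape indicator), `resid_sd`.
#' @export
assumption_checks <- function(fit, tail_ratio_bound = 1.5) {
  r <- stats::residuals(fit$model)
  f <- stats::fitted(fit$model)
  s <- stats::sd(r)
  z <- if (s > 0) (r - mean(r)) / s else r * 0
  n <- length(z)
  qq_cor <- stats::cor(sort(z), stats::qnorm(stats::ppoints(n)))
  # tail check on a robustly scaled residual: heavy tails inflate the plain
  # SD and would otherwise mask themselves
  s_rob <- stats::IQR(r) / 1.349
  if (!is.finite(s_rob) || s_rob == 0) s_rob <- max(s, .Machine$double.eps)
  z_rob <- (r - stats::median(r)) / s_rob
  p_tail <- 0.005
  obs <- stats::quantile(z_rob, c(p_tail, 1 - p_tail), names = FALSE)
  theo <- stats::qnorm(c(p_tail, 1 - p_tail))
  tail_ratio <- max(abs(obs) / abs(theo))
  tibble::tibble(
    qq_correlation = qq_cor,
    tail_ratio = tail_ratio,
    tails_flagged = tail_ratio > tail_ratio_bound,
    resid_fitted_cor = if (s > 0 && stats::sd(f) > 0)
      stats::cor(abs(r), f) else NA_real_,
    resid_sd = s
  )
}

#' Group comparison of circadian variables by relapse status
#'
#' Each participant contributes their study-period mean of each variable (one
#' value per participant), and the relapse and non-relapse groups are
#' compared with a two-tailed t-test plus the absolute pooled-SD standardized
#' mean difference (Cohen's d with unequal-n pooling).  Medians and IQRs are
#' also reported for use with non-symmetric variables.
#'
#' @param daily Labeled daily metrics (as for [build_observation_rows()]).
#' @param weekly Weekly metrics.
#' @param assignment [assign_relapse()] table.
#' @param variables Variables to compare (default all six).
#' @return Tibble, one row per variable: group sizes, means, SDs, medians,
#'   IQRs, `p_value`, `smd`.
#' @export
compare_groups <- function(daily, weekly, assignment,
                           variables = c("iv", "is", "l5", "m10", "ra",
                                         "wake_time")) {
  per_part <- function(variable) {
    src <- if (variable %in% c("is", "iv")) weekly else daily
    src |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(value = mean(.data[[variable]], na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::filter(is.finite(.data$value)) |>
      dplyr::inner_join(assignment[, c("participant_id", "relapsed")],
                        by = "participant_id")
  }
  purrr::map(variables, function(v) {
    d <- per_part(v)
    g1 <- d$value[!d$relapsed]   # did not relapse
    g2 <- d$value[d$relapsed]
    if (length(g1) == 0 || length(g2) == 0) {
      stop("both relapse groups must be nonempty", call. = FALSE)
    }
    p <- if (length(g1) >= 2 && length(g2) >= 2) {
      stats::t.test(g1, g2)$p.value
    } else {
      warning("group of size < 2 for ", v, ": p-value omitted")
      NA_real_
    }
    tibble::tibble(
      variable = v,
      n_nonrelapse = length(g1), n_relapse = length(g2),
      mean_nonrelapse = mean(g1), sd_nonrelapse = stats::sd(g1),
      mean_relapse = mean(g2), sd_relapse = stats::sd(g2),
      median_nonrelapse = stats::median(g1),
      iqr_nonrelapse = stats::IQR(g1),
      median_relapse = stats::median(g2),
      iqr_relapse = stats::IQR(g2),
      p_value = p,
      smd = cohens_d(g1, g2)
    )
  }) |>
    purrr::list_rbind()
}

#' Absolute pooled-SD standardized mean difference
#'
#' Cohen's d with unequal-n pooled SD, reported as a magnitude.
#'
#' @param x,y Numeric vectors (the two groups).
#' @return Non-negative scalar.
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  if (sp == 0) return(0)
  abs(mean(x) - mean(y)) / sp
}

`%||%` <- function(a, b) if (is.null(a)) b else a
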