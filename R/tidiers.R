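#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a circadian mixed-model fit
#'
#' One row per fixed-effect term: estimate, standard error, Wald statistic
#' (T for linear families, Z for the logistic), residual or Satterthwaite
#' degrees of freedom (linear only), p-value and 95% Wald interval; the
#' logistic family adds the odds ratio `exp(beta)`.
#'
#' @param x A `"circadian_fit"` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`, `df`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high` (+ `odds.ratio`).
#' @method tidy circadian_fit
#' @export
tidy.circadian_fit <- function(x, ...) {
  co <- summary(x$model)$coefficients
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  out <- tibble::tibble(
    term = rownames(co),
    estimate = unname(est),
    std.error = unname(se)
  )
  if (x$family == "relapse_prob") {
    z <- out$estimate / out$std.error
    out$df <- NA_real_
    out$statistic <- z
    out$p.value <- 2 * stats::pnorm(-abs(z))
    # Wald p is unreliable for the focal predictor here (boundary random
    # intercept); its p-value comes from the likelihood-ratio test
    if (!is.null(x$lrt_p)) out$p.value[out$term == x$focal_term] <- x$lrt_p
    out$odds.ratio <- exp(out$estimate)
  } else if (identical(x$ddf, "satterthwaite") && ncol(co) >= 5) {
    out$df <- unname(co[, "df"])
    out$statistic <- unname(co[, "t value"])
    out$p.value <- unname(co[, "Pr(>|t|)"])
  } else {
    df <- x$n_obs - nrow(co)   # residual counting
    tstat <- out$estimate / out$std.error
    out$df <- df
    out$statistic <- tstat
    out$p.value <- 2 * stats::pt(-abs(tstat), df = df)
  }
  out$conf.low <- out$estimate - stats::qnorm(0.975) * out$std.error
  out$conf.high <- out$estimate + stats::qnorm(0.975) * out$std.error
  out
}

#' Glance at a circadian mixed-model fit
#'
#' @param x A `"circadian_fit"` object.
#' @param ... Unused.
#' @return One-row tibble: family, sizes, random-intercept and residual SDs,
#'   log-likelihood, convergence flag.
#' @method glance circadian_fit
#' @export
glance.circadian_fit <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$model))
  ri_sd <- vc$sdcor[vc$grp == "participant_id"][1]
  res_sd <- if (any(vc$grp == "Residual")) vc$sdcor[vc$grp == "Residual"] else NA_real_
  tibble::tibble(
    family = x$family,
    n_obs = x$n_obs,
    n_participants = x$n_participants,
    sd_intercept = ri_sd,
    sd_residual = res_sd,
    logLik = as.numeric(stats::logLik(x$model)),
    converged = x$converged,
    n_flags = length(x$flags)
  )
}
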