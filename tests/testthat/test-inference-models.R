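test_that("discharge LMM recovers a programmed outpatient shift", {
  rows <- simulate_observations(
    n_participants = 36, n_inpatient_units = 5, n_outpatient_units = 7,
    intercept = 27840, effect_outpatient = 3600,
    sd_participant = 2000, sd_resid = 1500, seed = 101
  )
  fit <- fit_discharge_lmm(rows)
  est <- effect_estimate(fit)
  expect_lt(abs(est$estimate - 3600), 2 * est$std.error)
  expect_lt(est$p.value, 0.001)
  expect_equal(est$df, nrow(rows) - 2)
  expect_true(glance(fit)$converged)
})

test_that("degenerate and single-setting inputs are rejected", {
  rows <- simulate_observations(4, 2, 2, seed = 1)
  rows$value <- 5
  expect_error(fit_discharge_lmm(rows), "constant")
  rows2 <- simulate_observations(4, 0, 4, seed = 1)
  expect_error(fit_discharge_lmm(rows2), "both settings")
})

test_that("with no between-participant variance the LMM matches OLS on balanced data", {
  rows <- simulate_observations(
    n_participants = 30, n_inpatient_units = 4, n_outpatient_units = 4,
    intercept = 10, effect_outpatient = 2.5,
    sd_participant = 0, sd_resid = 1, seed = 7
  )
  fit <- fit_discharge_lmm(rows)
  est <- effect_estimate(fit)
  # closed-form two-group mean difference
  expect_equal(est$estimate,
               mean(rows$value[rows$outpatient == 1]) -
                 mean(rows$value[rows$outpatient == 0]),
               tolerance = 1e-6)
})

test_that("logistic relapse model is null under independence and signed under signal", {
  rows <- simulate_observations(
    n_participants = 103, n_outpatient_units = 4, relapse_fraction = 0.25,
    intercept = 0.4, sd_participant = 0.06, sd_resid = 0.03, seed = 11
  )
  rows <- rows[rows$post_relapse == 0, ]
  fit <- fit_relapse_logistic(rows)
  est <- effect_estimate(fit)
  expect_gt(est$p.value, 0.05)
  expect_true(est$odds.ratio > 0)
  expect_equal(est$odds.ratio, exp(est$estimate))

  # strongly predictive by construction: relapsers sit higher on x
  set.seed(12)
  rows2 <- rows
  rows2$value <- rows2$value + ifelse(rows2$relapsed, 0.4, 0)
  fit2 <- fit_relapse_logistic(rows2)
  expect_gt(effect_estimate(fit2)$estimate, 0)

  rows3 <- rows[!rows$relapsed, ]
  expect_error(fit_relapse_logistic(rows3), "both relapse outcomes")
})

test_that("relapse-effect LMM recovers programmed effects at the study magnitudes", {
  rows <- simulate_observations(
    n_participants = 103, n_inpatient_units = 2, n_outpatient_units = 28,
    relapse_fraction = 0.25,
    intercept = 27840, effect_outpatient = 3461, effect_post_relapse = 3190,
    sd_participant = 4000, sd_resid = 3000, seed = 21
  )
  fit <- fit_relapse_effect_lmm(rows)
  est <- effect_estimate(fit)
  expect_equal(est$term, "post_relapse")
  expect_lt(abs(est$estimate - 3190), 2 * est$std.error)

  rows_iv <- simulate_observations(
    n_participants = 103, n_inpatient_units = 1, n_outpatient_units = 4,
    relapse_fraction = 0.25,
    intercept = 0.45, effect_outpatient = -0.214, effect_post_relapse = -0.08,
    sd_participant = 0.10, sd_resid = 0.08, seed = 22
  )
  est_iv <- effect_estimate(fit_relapse_effect_lmm(rows_iv))
  expect_lt(abs(est_iv$estimate - (-0.08)), 2 * est_iv$std.error)
})

test_that("95% Wald intervals cover programmed effects at roughly the nominal rate", {
  set.seed(31)
  cover <- replicate(60, {
    rows <- simulate_observations(
      n_participants = 30, n_inpatient_units = 3, n_outpatient_units = 5,
      intercept = 0, effect_outpatient = 1,
      sd_participant = 1, sd_resid = 1
    )
    est <- effect_estimate(fit_discharge_lmm(rows))
    est$conf.low <= 1 && 1 <= est$conf.high
  })
  expect_gt(mean(cover), 0.85)
})

test_that("estimates are invariant to participant relabeling", {
  rows <- simulate_observations(20, 3, 5, intercept = 5, effect_outpatient = 1,
                                sd_participant = 1, sd_resid = 1, seed = 41)
  perm <- sample(unique(rows$participant_id))
  rows2 <- rows
  rows2$participant_id <- setNames(perm, unique(rows$participant_id))[rows$participant_id]
  e1 <- effect_estimate(fit_discharge_lmm(rows))
  e2 <- effect_estimate(fit_discharge_lmm(rows2))
  expect_equal(e1$estimate, e2$estimate, tolerance = 1e-8)
  expect_equal(e1$std.error, e2$std.error, tolerance = 1e-8)
})

test_that("assumption checks behave under gaussian, heavy-tailed and near-perfect fits", {
  rows <- simulate_observations(40, 5, 5, intercept = 0, effect_outpatient = 1,
                                sd_participant = 1, sd_resid = 1, seed = 51)
  fit <- fit_discharge_lmm(rows)
  chk <- assumption_checks(fit)
  expect_gt(chk$qq_correlation, 0.99)
  expect_false(chk$tails_flagged)

  set.seed(52)
  rows_t <- rows
  rows_t$value <- rows_t$outpatient + 0.5 * rt(nrow(rows_t), df = 2)
  chk_t <- assumption_checks(fit_discharge_lmm(rows_t))
  expect_true(chk_t$tails_flagged)

  rows_p <- rows
  rows_p$value <- 2 + 3 * rows_p$outpatient + rnorm(nrow(rows_p), 0, 1e-6)
  chk_p <- assumption_checks(fit_discharge_lmm(rows_p))
  expect_lt(chk_p$resid_sd, 1e-4)
})

test_that("group comparison reports t-test, SMD and pooled Cohen's d", {
  # identical group values: zero SMD, p = 1
  daily <- tibble::tibble(
    participant_id = sprintf("g%02d", 1:10),
    date = as.Date("2024-03-11"),
    m10 = rep(c(300, 310, 320, 330, 340), 2),
    l5 = 12, ra = 290, wake_time = 28000,
    week_index = 1L, setting = "outpatient", relapse_phase = "none"
  )
  weekly <- tibble::tibble(
    participant_id = daily$participant_id, week_index = 1L,
    setting = "outpatient", is = rep(c(0.1, 0.15, 0.2, 0.25, 0.3), 2),
    iv = 0.4, n_valid_days = 7L
  )
  assignment <- tibble::tibble(
    participant_id = daily$participant_id,
    relapsed = rep(c(FALSE, TRUE), each = 5),
    relapse_date = as.Date(NA), days_until_relapse = NA_integer_,
    total_drinks = 0L, heavy_drinking_days = 0L
  )
  cmp <- compare_groups(daily, weekly, assignment, variables = c("m10", "is"))
  expect_equal(cmp$smd, c(0, 0))
  expect_equal(cmp$p_value, c(1, 1))
  expect_equal(cmp$n_nonrelapse, c(5L, 5L))

  # closed-form Cohen's d with unequal-n pooling
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(4, 5, 6, 7)
  sp <- sqrt((5 * var(x) + 3 * var(y)) / 8)
  expect_equal(cohens_d(x, y), abs(mean(x) - mean(y)) / sp)
})

test_that("a programmed 1-hour wake difference is detected at the study group sizes", {
  set.seed(61)
  daily <- tibble::tibble(
    participant_id = sprintf("w%03d", 1:103),
    date = as.Date("2024-03-11"),
    m10 = 300, l5 = 12, ra = 288,
    wake_time = c(rnorm(77, 27840, 5340), rnorm(26, 27840 + 3600, 6240)),
    week_index = 1L, setting = "outpatient", relapse_phase = "none"
  )
  weekly <- tibble::tibble(participant_id = daily$participant_id,
                           week_index = 1L, setting = "outpatient",
                           is = 0.2, iv = 0.4, n_valid_days = 7L)
  assignment <- tibble::tibble(
    participant_id = daily$participant_id,
    relapsed = rep(c(FALSE, TRUE), c(77, 26)),
    relapse_date = as.Date(NA), days_until_relapse = NA_integer_,
    total_drinks = 0L, heavy_drinking_days = 0L
  )
  cmp <- compare_groups(daily, weekly, assignment, variables = "wake_time")
  expect_lt(cmp$p_value, 0.05)
  expect_gt(cmp$smd, 0.3)
})
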