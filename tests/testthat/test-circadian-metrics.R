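test_that("hourly summaries match direct per-hour averaging", {
  # constant week
  e <- multi_day_epochs(7, function(d) rep(10, 1440))
  h <- hourly_summaries(e)
  expect_true(all(h$hourly$mean == 10))
  expect_equal(unname(h$hour_of_day_means), rep(10, 24))
  expect_equal(h$overall_mean, 10)
  # one day, hour 0 all zeros, hour 1 all 60
  e2 <- one_day_epochs(c(rep(0, 60), rep(60, 60), rep(1, 1320)))
  h2 <- hourly_summaries(e2)
  expect_equal(h2$hourly$mean[1:2], c(0, 60))
  # random epochs vs brute force
  set.seed(5)
  e3 <- multi_day_epochs(3, function(d) rpois(1440, 20))
  e3$excluded <- runif(nrow(e3)) < 0.02
  h3 <- hourly_summaries(e3)
  ok <- e3[!e3$excluded, ]
  for (hr in c(0, 7, 23)) {
    for (d in unique(e3$date)) {
      sel <- ok$date == d & ok$minute %/% 60 == hr
      expect_equal(h3$hourly$mean[h3$hourly$date == d & h3$hourly$hour == hr],
                   mean(ok$count[sel]))
    }
  }
})

test_that("IS attains the sample-variance closed form on a periodic signal", {
  # hour-block profile repeating every 24 h, constant within hours, 7 days
  profile <- rep(c(0, 5, 40, 200, 250, 180, 90, 30), each = 3 * 60)
  e <- multi_day_epochs(7, function(d) profile)
  h <- hourly_summaries(e)
  is_val <- interdaily_stability(h)
  n <- 7 * 1440
  p <- 24
  expect_equal(is_val, (n - 1) * p / ((p - 1) * n), tolerance = 1e-12)
  expect_equal(is_val, oracle_is(e), tolerance = 1e-12)
})

test_that("IS is undefined on a constant signal and ~1/420 for white noise", {
  e <- multi_day_epochs(7, function(d) rep(7, 1440))
  expect_true(is.na(interdaily_stability(hourly_summaries(e))))
  set.seed(9)
  vals <- replicate(20, {
    en <- multi_day_epochs(7, function(d) rnorm(1440, 100, 10))
    interdaily_stability(hourly_summaries(en))
  })
  expect_equal(mean(vals), 1 / 420, tolerance = 0.25)
})

test_that("IV reproduces hand-derived values", {
  # constant hourly means: perfectly unfragmented
  e <- multi_day_epochs(7, function(d) rep(7, 1440))
  expect_equal(intradaily_variability(hourly_summaries(e)), 0)
  # 168 hourly means alternating 0 / 100
  alt <- multi_day_epochs(7, function(d) rep(rep(c(0, 100), 12), each = 60))
  iv <- intradaily_variability(hourly_summaries(alt))
  expect_equal(iv, 167 / 42, tolerance = 1e-12)   # = 10000 / (420000/167)
  expect_equal(iv, oracle_iv(alt), tolerance = 1e-12)
})

test_that("IV of white-noise hourly means is near 2", {
  set.seed(13)
  vals <- replicate(20, {
    # one draw per hour, repeated over the hour so hourly mean = the draw
    en <- multi_day_epochs(7, function(d) rep(rnorm(24, 100, 20), each = 60))
    intradaily_variability(hourly_summaries(en))
  })
  expect_equal(mean(vals), 2, tolerance = 0.1)
})

test_that("lag-1 pairs spanning an absent hour are skipped", {
  e <- multi_day_epochs(2, function(d) rep(rep(c(0, 100), 12), each = 60))
  # kill hour 5 of day 1: the 4-5 and 5-6 pairs must drop
  e$excluded[e$date == min(e$date) & e$minute %/% 60 == 5] <- TRUE
  h <- hourly_summaries(e)
  expect_equal(nrow(h$hourly), 47)
  expect_equal(intradaily_variability(h), oracle_iv(e), tolerance = 1e-12)
})

test_that("IS and IV are invariant under positive scaling of counts", {
  set.seed(21)
  e <- multi_day_epochs(7, function(d) rpois(1440, 30))
  h1 <- hourly_summaries(e)
  e2 <- e
  e2$count <- e2$count * 3.7
  h2 <- hourly_summaries(e2)
  expect_equal(interdaily_stability(h1), interdaily_stability(h2))
  expect_equal(intradaily_variability(h1), intradaily_variability(h2))
})

test_that("M10/L5/RA follow the ranking definition", {
  # active 100/min in hours 8-17, zero elsewhere
  counts <- rep(0, 1440)
  counts[(8 * 60 + 1):(18 * 60)] <- 100
  r <- daily_m10_l5_ra(one_day_epochs(counts))
  expect_equal(r$m10, 6000)    # hourly totals of 100/min
  expect_equal(r$l5, 0)
  expect_equal(r$ra, 6000)
  # hourly totals h+1 for h = 0..23 (via constant minutes (h+1)/60)
  counts2 <- rep((1:24) / 60, each = 60)
  r2 <- daily_m10_l5_ra(one_day_epochs(counts2))
  expect_equal(r2$m10, 19.5)
  expect_equal(r2$l5, 3)
  expect_equal(r2$ra, 16.5)
})

test_that("M10/L5 match the sort oracle on random days, with rescaled partial hours", {
  set.seed(31)
  for (i in 1:25) {
    counts <- rpois(1440, sample(c(5, 50, 300), 1))
    excl <- runif(1440) < 0.05
    day <- one_day_epochs(counts, excluded = excl)
    r <- daily_m10_l5_ra(day)
    o <- oracle_m10_l5(day)
    expect_equal(r$m10, unname(o["m10"]))
    expect_equal(r$l5, unname(o["l5"]))
    expect_gte(r$ra, 0)
  }
  # fewer than 15 computable hours: skipped with NA metrics
  sparse <- one_day_epochs(rpois(1440, 10),
                           excluded = rep(c(FALSE, TRUE), c(10 * 60, 1440 - 600)))
  r <- daily_m10_l5_ra(sparse)
  expect_true(is.na(r$m10) && is.na(r$ra))
  expect_equal(r$n_hours, 10L)
})

test_that("weekly metrics require four valid days and split by setting", {
  set.seed(41)
  e <- multi_day_epochs(10, function(d) rpois(1440, 50) + rep(c(0, 200), c(480, 960)))
  vd <- day_validity(e)
  labels <- tibble::tibble(
    participant_id = "p1", date = sort(unique(e$date)),
    week_index = rep(c(2L, 1L), c(3, 7)),
    setting = rep(c("inpatient", "outpatient"), c(3, 7)),
    relapse_phase = "none"
  )
  wm <- compute_weekly_metrics(e, labels)
  # 3-day inpatient group is dropped, 7-day outpatient week kept
  expect_equal(nrow(wm), 1)
  expect_equal(wm$setting, "outpatient")
  expect_equal(wm$n_valid_days, 7L)
  expect_true(is.finite(wm$is) && is.finite(wm$iv))
})
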