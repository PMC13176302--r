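mk_manifest <- function(ids, sex = "female",
                        discharge = as.Date("2024-03-10")) {
  tibble::tibble(participant_id = ids, discharge_date = discharge,
                 sex = rep_len(sex, length(ids)))
}

mk_diary <- function(id, discharge, drinks_by_day) {
  tibble::tibble(
    participant_id = id,
    date = discharge + seq_along(drinks_by_day),
    bed_time = "23:00", wake_time = "07:00",
    drinks = as.integer(drinks_by_day)
  )
}

test_that("relapse assignment follows the any-alcohol rule with sex-specific heavy days", {
  dis <- as.Date("2024-03-10")
  man <- mk_manifest(c("f1", "m1", "n1"), sex = c("female", "male", "female"))
  diaries <- dplyr::bind_rows(
    mk_diary("f1", dis, c(rep(0, 10), 4, rep(0, 17))),   # 4 drinks on day 11
    mk_diary("m1", dis, rep(4, 28)),                     # male, daily 4
    mk_diary("n1", dis, rep(0, 28))
  )
  a <- assign_relapse(diaries, man)
  f1 <- a[a$participant_id == "f1", ]
  expect_true(f1$relapsed)
  expect_equal(f1$days_until_relapse, 11L)
  expect_equal(f1$heavy_drinking_days, 1L)    # 4 drinks meets the female threshold
  m1 <- a[a$participant_id == "m1", ]
  expect_true(m1$relapsed)
  expect_equal(m1$days_until_relapse, 1L)
  expect_equal(m1$heavy_drinking_days, 0L)    # male threshold is 5
  expect_equal(m1$total_drinks, 4L * 28L)
  n1 <- a[a$participant_id == "n1", ]
  expect_false(n1$relapsed)
  expect_equal(n1$total_drinks, 0L)
  expect_true(is.na(n1$relapse_date))
})

test_that("drinking outside the follow-up window does not count", {
  dis <- as.Date("2024-03-10")
  man <- mk_manifest("p1")
  d <- mk_diary("p1", dis, rep(0, 30))
  d$drinks[d$date == dis + 29] <- 6L       # day 29: beyond the window
  a <- assign_relapse(d, man, followup_days = 28)
  expect_false(a$relapsed)
})

test_that("missing diary is an upstream-exclusion error", {
  man <- mk_manifest(c("p1", "p2"))
  d <- mk_diary("p1", as.Date("2024-03-10"), rep(0, 28))
  expect_error(assign_relapse(d, man), "p2")
})

test_that("weeks count backward from the anchor", {
  dis <- as.Date("2024-03-01")
  man <- mk_manifest("r1", discharge = dis)
  # 28 recorded days starting on discharge+1; relapse on study day 15
  dates <- dis + 1:28
  vd <- tibble::tibble(participant_id = "r1", date = dates,
                       missing_minutes = 0L, valid = TRUE)
  a <- tibble::tibble(participant_id = "r1", relapsed = TRUE,
                      relapse_date = dis + 15, days_until_relapse = 15L,
                      total_drinks = 3L, heavy_drinking_days = 0L)
  lab <- index_weeks(vd, a, man)
  # days 8..14 are week 1; day 15 opens week 0
  expect_equal(unique(lab$week_index[lab$date %in% (dis + 8:14)]), 1L)
  expect_equal(lab$week_index[lab$date == dis + 15], 0L)
  expect_equal(lab$relapse_phase[lab$date == dis + 15], "post")
  expect_equal(lab$relapse_phase[lab$date == dis + 14], "pre")
  expect_equal(unique(lab$week_index[lab$date %in% (dis + 1:7)]), 2L)
  expect_equal(unique(lab$week_index[lab$date %in% (dis + 22:28)]), -1L)

  # non-relapser: final 7 days are week 1
  a0 <- a
  a0$relapsed <- FALSE
  a0$relapse_date <- as.Date(NA)
  lab0 <- index_weeks(vd, a0, man)
  expect_equal(unique(lab0$week_index[lab0$date %in% (dis + 22:28)]), 1L)
  expect_equal(unique(lab0$week_index[lab0$date %in% (dis + 15:21)]), 2L)
  expect_true(all(lab0$relapse_phase == "none"))
})

test_that("every valid day gets exactly one label triple", {
  dis <- as.Date("2024-03-05")
  man <- mk_manifest("r1", discharge = dis)
  dates <- dis - 3 + 0:20
  vd <- tibble::tibble(participant_id = "r1", date = dates,
                       missing_minutes = 0L,
                       valid = rep(c(TRUE, FALSE), length.out = 21))
  a <- tibble::tibble(participant_id = "r1", relapsed = TRUE,
                      relapse_date = dis + 9, days_until_relapse = 9L,
                      total_drinks = 1L, heavy_drinking_days = 0L)
  lab <- index_weeks(vd, a, man)
  expect_equal(nrow(lab), sum(vd$valid))
  expect_equal(anyDuplicated(lab[, c("participant_id", "date")]), 0L)
  expect_true(all(lab$setting[lab$date <= dis] == "inpatient"))
  expect_true(all(lab$setting[lab$date > dis] == "outpatient"))
})

test_that("relapse before any actigraphy is rejected", {
  dis <- as.Date("2024-03-01")
  man <- mk_manifest("r1", discharge = dis)
  vd <- tibble::tibble(participant_id = "r1", date = dis + 10:20,
                       missing_minutes = 0L, valid = TRUE)
  a <- tibble::tibble(participant_id = "r1", relapsed = TRUE,
                      relapse_date = dis + 2, days_until_relapse = 2L,
                      total_drinks = 1L, heavy_drinking_days = 0L)
  expect_error(index_weeks(vd, a, man), "precedes")
})

test_that("inpatient subset matches a brute-force recount", {
  dis <- as.Date("2024-03-10")
  set.seed(8)
  n <- 20
  ids <- sprintf("s%02d", 1:n)
  inpat <- sample(0:7, n, replace = TRUE)
  labels <- purrr::map2(ids, inpat, function(id, k) {
    dates <- c(dis - rev(seq_len(k)) + 1, dis + 1:14)
    tibble::tibble(participant_id = id, date = dates,
                   week_index = 1L,
                   setting = ifelse(dates <= dis, "inpatient", "outpatient"),
                   relapse_phase = "none")
  }) |> purrr::list_rbind()
  man <- mk_manifest(ids, discharge = dis)
  sub <- inpatient_subset(labels, man, min_inpatient_days = 4)
  expect_setequal(sub$participants, ids[inpat >= 4])
  # subset spans only inpatient days and the first outpatient week
  expect_true(all(sub$day_labels$date <= dis + 7))
  # a 2-day inpatient participant is out of the subset but keeps daily rows upstream
  expect_false(any(ids[inpat == 2] %in% sub$participants))
})

test_that("observation rows carry the family-specific subsets and indicators", {
  daily <- tibble::tibble(
    participant_id = rep(c("r1", "n1"), each = 10),
    date = rep(as.Date("2024-03-11") + 0:9, 2),
    m10 = rnorm(20, 300, 10), l5 = rnorm(20, 12, 2), ra = 290,
    wake_time = rnorm(20, 28000, 500),
    week_index = rep(rep(2:1, each = 5), 2),
    setting = "outpatient",
    relapse_phase = c(rep("pre", 5), rep("post", 5), rep("none", 10))
  )
  weekly <- tibble::tibble(
    participant_id = rep(c("r1", "n1"), each = 2),
    week_index = rep(c(1L, 0L), 2),
    setting = "outpatient",
    is = runif(4, 0.1, 0.3), iv = runif(4, 0.3, 0.5), n_valid_days = 7L
  )
  assignment <- tibble::tibble(
    participant_id = c("r1", "n1"), relapsed = c(TRUE, FALSE),
    relapse_date = c(as.Date("2024-03-16"), NA),
    days_until_relapse = c(5L, NA), total_drinks = c(4L, 0L),
    heavy_drinking_days = 0L
  )
  # relapse-probability family: relapser rows end the day before relapse
  rp <- build_observation_rows(daily, weekly, assignment, "wake_time",
                               "relapse_prob")
  expect_true(all(rp$post_relapse == 0))
  expect_equal(sum(rp$participant_id == "r1"), 5)
  expect_equal(sum(rp$participant_id == "n1"), 10)
  expect_true(all(rp$relapsed[rp$participant_id == "r1"]))
  # relapse-effect family: the relapse day itself is post
  re <- build_observation_rows(daily, weekly, assignment, "wake_time",
                               "relapse_effect")
  expect_equal(sum(re$post_relapse), 5)
  expect_true(all(re$post_relapse[re$participant_id == "n1"] == 0))
  # weekly variables take one row per week with week-0 post for relapsers
  rw <- build_observation_rows(daily, weekly, assignment, "iv",
                               "relapse_effect")
  expect_equal(nrow(rw), 4)
  expect_equal(rw$post_relapse[rw$participant_id == "r1" & rw$unit == 0L], 1L)
  expect_equal(sum(rw$post_relapse), 1L)
  expect_error(build_observation_rows(daily, weekly, assignment, "bogus",
                                      "discharge"),
               "should be one of")
})
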