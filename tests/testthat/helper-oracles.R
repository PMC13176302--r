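# Independent brute-force oracles, deliberately written as plain loops over
# the defining formulas, sharing no code with the package implementation.

# epochs: tibble with date, minute, count, excluded
oracle_is <- function(epochs) {
  ok <- epochs[!epochs$excluded, ]
  x <- ok$count
  hour <- ok$minute %/% 60
  xbar <- mean(x)
  hod <- sort(unique(hour))
  xh <- vapply(hod, function(h) mean(x[hour == h]), numeric(1))
  p <- length(xh)
  num <- 0
  for (h in seq_len(p)) num <- num + (xh[h] - xbar)^2
  num <- num / (p - 1)
  den <- 0
  for (i in seq_along(x)) den <- den + (x[i] - xbar)^2
  den <- den / (length(x) - 1)
  num / den
}

oracle_iv <- function(epochs, min_valid_min = 30) {
  ok <- epochs[!epochs$excluded, ]
  key <- paste(ok$date, ok$minute %/% 60)
  tab <- unique(data.frame(date = ok$date, hour = ok$minute %/% 60))
  tab <- tab[order(tab$date, tab$hour), ]
  means <- numeric(0); times <- numeric(0)
  for (r in seq_len(nrow(tab))) {
    sel <- ok$date == tab$date[r] & ok$minute %/% 60 == tab$hour[r]
    if (sum(sel) >= min_valid_min) {
      means <- c(means, mean(ok$count[sel]))
      times <- c(times, as.numeric(tab$date[r]) * 24 + tab$hour[r])
    }
  }
  n_h <- length(means)
  if (n_h < 3) return(NA_real_)
  num <- 0; npairs <- 0
  for (j in 2:n_h) {
    if (times[j] - times[j - 1] == 1) {
      num <- num + (means[j] - means[j - 1])^2
      npairs <- npairs + 1
    }
  }
  if (npairs == 0) return(NA_real_)
  num <- num / npairs
  if (num == 0) return(0)
  m <- mean(means)
  den <- 0
  for (j in seq_len(n_h)) den <- den + (means[j] - m)^2
  den <- den / (n_h - 1)
  num / den
}

# one day's epochs -> c(m10, l5) using rank ordering over hourly totals
oracle_m10_l5 <- function(day_epochs, min_valid_min = 30) {
  ok <- day_epochs[!day_epochs$excluded, ]
  hour <- ok$minute %/% 60
  totals <- numeric(0)
  for (h in 0:23) {
    n <- sum(hour == h)
    if (n >= min_valid_min) {
      totals <- c(totals, sum(ok$count[hour == h]) * 60 / n)
    }
  }
  ord <- order(totals, decreasing = TRUE)
  m10 <- mean(totals[ord[1:10]])
  l5 <- mean(totals[rev(ord)[1:5]])
  c(m10 = m10, l5 = l5)
}

# a full-day epoch tibble from a 1440-vector of counts
one_day_epochs <- function(counts, date = as.Date("2024-03-01"),
                           excluded = FALSE, id = "p1") {
  tibble::tibble(
    participant_id = id,
    datetime = as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + 60 * (0:1439),
    date = date,
    minute = 0:1439,
    count = counts,
    excluded = rep_len(excluded, 1440)
  )
}

# n_days consecutive full days from a function day -> counts vector
multi_day_epochs <- function(n_days, counts_fn,
                             start = as.Date("2024-03-01"), id = "p1") {
  purrr::map(seq_len(n_days), function(d) {
    one_day_epochs(counts_fn(d), date = start + d - 1, id = id)
  }) |>
    purrr::list_rbind()
}
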