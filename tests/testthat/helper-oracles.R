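# Independent oracles kept deliberately naive; they never share code with
# the implementation paths they check.

# closed-form normal-equations OLS: b = S_xy / S_xx, a = ybar - b * xbar
ols_oracle <- function(d, y) {
  db <- mean(d)
  yb <- mean(y)
  b <- sum((d - db) * (y - yb)) / sum((d - db)^2)
  c(intercept = yb - b * db, slope = b)
}

# linear-interpolation percentile: h = (n - 1) * p + 1 on the sorted values
percentile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# readings-table builder: one user, one reading per element of `day`
make_readings <- function(user_id, day, bg, start = "2020-01-01",
                          frac = 0.5) {
  t0 <- as.POSIXct(start, tz = "UTC")
  tibble::tibble(
    user_id = user_id,
    timestamp = t0 + (day + frac) * 86400,
    bg = bg
  )
}

# engagement-record builder in monthly_engagement's output shape
make_engagement <- function(user_id, logging_days,
                            entries = logging_days,
                            start = as.Date("2020-01-01")) {
  m <- seq_along(logging_days)
  tibble::tibble(
    user_id = user_id,
    month_index = m,
    month_start = start + (m - 1L) * 30L,
    logging_days = as.integer(logging_days),
    entries = as.integer(entries)
  )
}

# minimal complying profile table
make_profiles <- function(user_ids, diabetes_type = "T1DM", age = 40,
                          years = 10, complications = "none") {
  tibble::tibble(
    user_id = user_ids,
    diabetes_type = diabetes_type,
    sex = "female",
    age = age,
    bmi = 24,
    years_diagnosed = years,
    complications = complications
  )
}
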