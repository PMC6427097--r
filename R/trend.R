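#' Least-squares glycemic level at a window's start
#'
#' Fits an ordinary least-squares line to one user's readings inside a
#' half-open time window, with fractional days since `window_start` as the
#' predictor. The fitted intercept is reported as the blood-glucose level
#' at the window's first instant; extrapolation to the window start makes
#' the estimate insensitive to where inside the window the readings fall.
#'
#' @param readings Tibble with `timestamp` and `bg` for a single user (a
#'   `user_id` column, if present, is ignored).
#' @param window_start Start of the window (POSIXct/Date/ISO string).
#' @param window_days Window length in days (default 30, one rolling
#'   month).
#' @param min_readings Minimum readings required for a fit; windows with
#'   fewer are flagged rather than fitted (default 5, consistent with the
#'   5-logging-days-per-month inclusion floor).
#' @return One-row tibble: `n_readings`, `bg_estimate` (intercept, mg/dL),
#'   `slope` (mg/dL per day), `flagged` (TRUE when `n_readings <
#'   min_readings`; estimates are `NA`). With a single distinct time point
#'   the slope is 0 and the intercept is the mean reading.
#' @export
fit_window <- function(readings, window_start, window_days = 30,
                       min_readings = 5L) {
  stopifnot(all(c("timestamp", "bg") %in% names(readings)))
  window_start <- as_utc(window_start)
  d <- days_between(readings$timestamp, window_start)
  keep <- d >= 0 & d < window_days
  ols_window(d[keep], readings$bg[keep], min_readings)
}

# OLS on (days, bg); QR factorization via stats::lm.fit.
ols_window <- function(d, bg, min_readings) {
  n <- length(bg)
  if (n < min_readings) {
    return(tibble(n_readings = n, bg_estimate = NA_real_,
                  slope = NA_real_, flagged = TRUE))
  }
  # exactly constant readings (or a single distinct time) admit an exact
  # fit; bypass the QR path so no float dust leaks into paired differences
  if (length(unique(d)) < 2L || length(unique(bg)) < 2L) {
    return(tibble(n_readings = n, bg_estimate = mean(bg), slope = 0,
                  flagged = FALSE))
  }
  co <- lm.fit(cbind(intercept = rep(1, n), day = d), bg)$coefficients
  tibble(n_readings = n, bg_estimate = unname(co[1]),
         slope = unname(co[2]), flagged = FALSE)
}

#' Baseline, month-3 and month-6 glycemic levels per user
#'
#' Estimates each user's blood-glucose level at baseline, month 3 and
#' month 6 as the regression intercepts of the readings of analysis months
#' 1, 4 and 7 respectively (30-day months counted from the user's
#' engagement anchor). Windows failing `min_readings` are flagged; the
#' user drops out of that timepoint's comparison only.
#'
#' @param readings Tibble with `user_id`, `timestamp`, `bg`.
#' @param anchors Tibble with `user_id` and `anchor` (start of analysis
#'   month 1, typically the start of the qualifying engagement span).
#' @param window_days Month length in days (default 30).
#' @param min_readings Per-window minimum reading count (default 5).
#' @param months Named integer vector mapping timepoint labels to analysis
#'   month indices.
#' @return Tibble with one row per user and timepoint: `user_id`,
#'   `timepoint`, `window_start`, `n_readings`, `bg_estimate`, `slope`,
#'   `flagged`.
#' @export
bg_trajectory <- function(readings, anchors, window_days = 30,
                          min_readings = 5L,
                          months = c(baseline = 1L, month3 = 4L, month6 = 7L)) {
  stopifnot(all(c("user_id", "timestamp", "bg") %in% names(readings)),
            all(c("user_id", "anchor") %in% names(anchors)))
  anchors <- mutate(anchors, anchor = as_utc(.data$anchor))
  grid <- tidyr::crossing(
    anchors["user_id"],
    tibble(timepoint = names(months), month = unname(months))
  ) |>
    left_join(anchors, by = "user_id") |>
    mutate(
      window_start = .data$anchor + (.data$month - 1L) * window_days * 86400,
      window_end   = .data$window_start + window_days * 86400
    )

  hits <- inner_join(
    mutate(readings, timestamp = as_utc(.data$timestamp)),
    grid,
    by = join_by("user_id", "timestamp" >= "window_start", "timestamp" < "window_end")
  )
  fits <- hits |>
    mutate(d = days_between(.data$timestamp, .data$window_start)) |>
    group_by(.data$user_id, .data$timepoint, .data$window_start) |>
    reframe(ols_window(.data$d, .data$bg, min_readings))

  # windows with zero readings produce no hit rows; restore them as flagged
  grid |>
    select("user_id", "timepoint", "window_start") |>
    left_join(fits, by = c("user_id", "timepoint", "window_start")) |>
    mutate(
      n_readings = dplyr::coalesce(.data$n_readings, 0L),
      flagged = dplyr::coalesce(.data$flagged, TRUE)
    ) |>
    arrange(.data$user_id, .data$timepoint)
}
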