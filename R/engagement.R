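#' Engagement inclusion and stratification criteria
#'
#' Bundles the app-usage rules used to include users and split them into
#' high- and low-engagement groups: the inclusion floor (at least
#' `min_days_per_month` distinct logging days in each of `min_months`
#' consecutive months) and the stratification thresholds.
#'
#' Inclusion always counts distinct logging days. Group assignment counts
#' either days or total entries per month, controlled by `counting_mode`;
#' entry counting is required when the high-engagement threshold exceeds the
#' length of a month in days (e.g. 60 logs/month).
#'
#' @param min_days_per_month Inclusion floor, distinct logging days per
#'   month (study value 5).
#' @param min_months Number of consecutive qualifying months required
#'   (study value 6).
#' @param high_threshold Per-month count at or above which a user is
#'   high-engagement for every month of the qualifying span (15 for the
#'   glycated-hemoglobin analysis, 60 for the risk-index analysis).
#' @param low_range Inclusive per-month count range defining the nominal
#'   low-engagement band (study value 5-10).
#' @param counting_mode `"days"` (distinct logging days) or `"entries"`
#'   (total readings) for group assignment.
#' @param strict If `FALSE` (default), every included user who is not
#'   high-engagement is assigned to the low-engagement group, matching the
#'   study's complementary group sizes. If `TRUE`, users whose counts fall
#'   between `low_range` and `high_threshold` are excluded instead.
#' @return An object of class `engagement_criteria`.
#' @examples
#' engagement_criteria() # analysis-1 defaults
#' engagement_criteria(high_threshold = 60, counting_mode = "entries")
#' @export
engagement_criteria <- function(min_days_per_month = 5L,
                                min_months = 6L,
                                high_threshold = 15L,
                                low_range = c(5L, 10L),
                                counting_mode = c("days", "entries"),
                                strict = FALSE) {
  counting_mode <- match.arg(counting_mode)
  stopifnot(min_months >= 1L, min_days_per_month >= 0L, length(low_range) == 2L)
  if (high_threshold <= low_range[2]) {
    abort("high_threshold must exceed the upper bound of low_range")
  }
  if (counting_mode == "days" && high_threshold > 31) {
    abort("high_threshold exceeds the length of a month in days; use counting_mode = 'entries'")
  }
  structure(
    list(
      min_days_per_month = as.integer(min_days_per_month),
      min_months = as.integer(min_months),
      high_threshold = as.integer(high_threshold),
      low_range = as.integer(low_range),
      counting_mode = counting_mode,
      strict = strict
    ),
    class = "engagement_criteria"
  )
}

#' @export
print.engagement_criteria <- function(x, ...) {
  cat(sprintf(
    "<engagement_criteria> inclusion: >=%d days/month for >=%d consecutive months\n",
    x$min_days_per_month, x$min_months
  ))
  cat(sprintf(
    "  groups (%s/month): high >= %d; low band %d-%d (%s)\n",
    x$counting_mode, x$high_threshold, x$low_range[1], x$low_range[2],
    if (x$strict) "strict: in-between excluded" else "inclusive: non-high -> low"
  ))
  invisible(x)
}

#' Per-user, per-month app-usage summaries
#'
#' Counts distinct logging days and total entries in each of a user's
#' months, from the month of the first reading to the month of the last.
#' Months with no readings appear with zero counts, so month indices are
#' always contiguous.
#'
#' @param readings Tibble with `user_id`, `timestamp`, `bg`. Order is
#'   irrelevant.
#' @param month_scheme `"rolling30"` (30-day windows anchored at the user's
#'   first reading day, the default: months 1/4/7 are well defined for every
#'   user) or `"calendar"` (calendar months).
#' @return Tibble with `user_id`, `month_index` (1 = first observation
#'   month), `month_start` (date), `logging_days`, `entries`.
#' @export
monthly_engagement <- function(readings, month_scheme = c("rolling30", "calendar")) {
  month_scheme <- match.arg(month_scheme)
  stopifnot(all(c("user_id", "timestamp") %in% names(readings)))
  if (nrow(readings) == 0L) {
    return(tibble(
      user_id = character(), month_index = integer(),
      month_start = as.Date(character()), logging_days = integer(),
      entries = integer()
    ))
  }
  rd <- readings |>
    mutate(.date = as.Date(as_utc(.data$timestamp)))

  if (month_scheme == "rolling30") {
    rd <- rd |>
      group_by(.data$user_id) |>
      mutate(
        .anchor = min(.data$.date),
        month_index = as.integer(as.numeric(.data$.date - .data$.anchor) %/% 30L) + 1L,
        month_start = .data$.anchor + (.data$month_index - 1L) * 30L
      ) |>
      ungroup()
  } else {
    first_of_month <- function(d) as.Date(format(d, "%Y-%m-01"))
    rd <- rd |>
      group_by(.data$user_id) |>
      mutate(
        .anchor = first_of_month(min(.data$.date)),
        month_start = first_of_month(.data$.date),
        month_index = 1L + 12L * (as.integer(format(.data$.date, "%Y")) -
                                    as.integer(format(.data$.anchor, "%Y"))) +
          (as.integer(format(.data$.date, "%m")) -
             as.integer(format(.data$.anchor, "%m")))
      ) |>
      ungroup()
  }

  counts <- rd |>
    group_by(.data$user_id, .data$month_index) |>
    summarise(
      month_start = .data$month_start[1],
      logging_days = dplyr::n_distinct(.data$.date),
      entries = dplyr::n(),
      .groups = "drop"
    )

  anchors <- rd |>
    group_by(.data$user_id) |>
    summarise(.anchor = .data$.anchor[1], .scheme_last = max(.data$month_index),
              .groups = "drop")

  # fill months with no readings so indices are contiguous per user
  full <- counts |>
    group_by(.data$user_id) |>
    tidyr::complete(month_index = seq_len(max(.data$month_index)),
                    fill = list(logging_days = 0L, entries = 0L)) |>
    ungroup() |>
    left_join(anchors, by = "user_id")

  if (month_scheme == "rolling30") {
    full <- full |>
      mutate(month_start = .data$.anchor + (.data$month_index - 1L) * 30L)
  } else {
    full <- full |>
      mutate(month_start = dplyr::coalesce(
        .data$month_start,
        as.Date(vapply(seq_len(dplyr::n()), function(i) {
          d <- seq(.anchor[i], by = "month", length.out = month_index[i])
          as.character(d[length(d)])
        }, character(1)))
      ))
  }
  full |>
    select("user_id", "month_index", "month_start", "logging_days", "entries") |>
    arrange(.data$user_id, .data$month_index)
}

#' Engagement-based inclusion test
#'
#' A user is included when there exist at least `min_months` *consecutive*
#' months, each with at least `min_days_per_month` distinct logging days.
#' The earliest such span anchors the user's analysis window: months 1-7 of
#' the analyses are counted from its start.
#'
#' @param engagement Output of [monthly_engagement()].
#' @param criteria An [engagement_criteria()] object.
#' @return Tibble with `user_id`, `eligible` (logical), `span_start`
#'   (month index of the earliest qualifying span; `NA` when ineligible).
#' @export
passes_inclusion <- function(engagement, criteria = engagement_criteria()) {
  stopifnot(inherits(criteria, "engagement_criteria"))
  m <- criteria$min_months
  engagement |>
    group_by(.data$user_id) |>
    arrange(.data$month_index, .by_group = TRUE) |>
    summarise(
      span_start = {
        ok <- .data$logging_days >= criteria$min_days_per_month
        first_run_start(ok, m)
      },
      .groups = "drop"
    ) |>
    mutate(eligible = !is.na(.data$span_start)) |>
    select("user_id", "eligible", "span_start")
}

# index of the first position starting a run of >= m consecutive TRUEs
first_run_start <- function(ok, m) {
  n <- length(ok)
  if (n < m) return(NA_integer_)
  cs <- cumsum(as.integer(ok))
  wins <- cs[m:n] - c(0L, cs)[1:(n - m + 1L)]
  hit <- which(wins == m)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Assign included users to engagement strata
#'
#' A user is high-engagement (group `"A"`) when the per-month count (days
#' or entries, per the criteria's `counting_mode`) meets `high_threshold`
#' in *every* month of the qualifying span. Under the default inclusive
#' rule every other included user is low-engagement (group `"B"`); under
#' `strict = TRUE` users outside the nominal low band in any span month are
#' `"excluded"`. Ineligible users are always `"excluded"`. Behaviour after
#' the qualifying span is ignored.
#'
#' @inheritParams passes_inclusion
#' @param inclusion Output of [passes_inclusion()]; computed when `NULL`.
#' @return Tibble with `user_id`, `group` in `"A"`, `"B"`, `"excluded"`,
#'   and `span_start`.
#' @export
assign_group <- function(engagement, criteria = engagement_criteria(),
                         inclusion = NULL) {
  stopifnot(inherits(criteria, "engagement_criteria"))
  if (is.null(inclusion)) {
    inclusion <- passes_inclusion(engagement, criteria)
  }
  span <- engagement |>
    inner_join(inclusion, by = "user_id") |>
    filter(.data$eligible,
           .data$month_index >= .data$span_start,
           .data$month_index < .data$span_start + criteria$min_months) |>
    mutate(count = if (criteria$counting_mode == "days") .data$logging_days else .data$entries) |>
    group_by(.data$user_id) |>
    summarise(
      all_high = all(.data$count >= criteria$high_threshold),
      all_low  = all(.data$count >= criteria$low_range[1] &
                       .data$count <= criteria$low_range[2]),
      .groups = "drop"
    )
  inclusion |>
    left_join(span, by = "user_id") |>
    mutate(group = dplyr::case_when(
      !.data$eligible ~ "excluded",
      .data$all_high ~ "A",
      criteria$strict & !.data$all_low ~ "excluded",
      .default = "B"
    )) |>
    select("user_id", "group", "span_start")
}
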