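test_that("monthly summaries count distinct days and entries per rolling month", {
  daily <- make_readings("u1", day = 0:209, bg = 150)
  m <- monthly_engagement(daily)
  expect_equal(nrow(m), 7L)
  expect_equal(m$month_index, 1:7)
  expect_true(all(m$logging_days == 30L))
  expect_true(all(m$entries == 30L))

  triple <- make_readings("u1", day = c(3, 3, 3), bg = 150)
  m3 <- monthly_engagement(triple)
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$logging_days, 1L)
  expect_equal(m3$entries, 3L)

  four_per_window <- make_readings(
    "u1", day = as.vector(outer(0:3, (0:6) * 30, "+")), bg = 150
  )
  m4 <- monthly_engagement(four_per_window)
  expect_equal(m4$logging_days, rep(4L, 7))
})

test_that("months with no readings appear with zero counts", {
  gappy <- make_readings("u1", day = c(0, 5, 70), bg = 150)
  m <- monthly_engagement(gappy)
  expect_equal(m$month_index, 1:3)
  expect_equal(m$logging_days, c(2L, 0L, 1L))
  expect_equal(m$entries, c(2L, 0L, 1L))
})

test_that("summaries are invariant to reading order and empty input is empty", {
  rd <- make_readings("u1", day = sample(0:100, 60, replace = TRUE), bg = 150)
  shuffled <- rd[sample(nrow(rd)), ]
  expect_equal(monthly_engagement(rd), monthly_engagement(shuffled))
  expect_equal(nrow(monthly_engagement(rd[0, ])), 0L)
})

test_that("calendar month scheme groups by calendar month", {
  rd <- make_readings("u1", day = c(0, 20, 40, 70), bg = 150,
                      start = "2020-01-15")
  m <- monthly_engagement(rd, month_scheme = "calendar")
  # Jan 15, Feb 4, Feb 24, Mar 25
  expect_equal(m$month_index, 1:3)
  expect_equal(m$entries, c(1L, 2L, 1L))
})

test_that("inclusion needs the qualifying months to be consecutive", {
  crit <- engagement_criteria()

  perfect <- make_engagement("u1", rep(30, 7))
  p <- passes_inclusion(perfect, crit)
  expect_true(p$eligible)
  expect_equal(p$span_start, 1L)

  broken <- make_engagement("u1", c(30, 30, 4, 30, 30, 30))
  expect_false(passes_inclusion(broken, crit)$eligible)

  exactly_six <- make_engagement("u1", c(5, 5, 5, 5, 5, 5, 0))
  expect_true(passes_inclusion(exactly_six, crit)$eligible)

  late_span <- make_engagement("u1", c(2, 0, rep(6, 6)))
  p2 <- passes_inclusion(late_span, crit)
  expect_true(p2$eligible)
  expect_equal(p2$span_start, 3L)
})

test_that("group assignment follows the high threshold over the whole span", {
  crit <- engagement_criteria(high_threshold = 15)
  expect_equal(assign_group(make_engagement("u1", rep(20, 6)), crit)$group, "A")
  expect_equal(assign_group(make_engagement("u1", rep(7, 6)), crit)$group, "B")
  # between the low band and the high threshold: low group under the
  # inclusive default, excluded under the strict rule
  mid <- make_engagement("u1", rep(12, 6))
  expect_equal(assign_group(mid, crit)$group, "B")
  strict <- engagement_criteria(high_threshold = 15, strict = TRUE)
  expect_equal(assign_group(mid, strict)$group, "excluded")
  # one span month below the threshold denies A
  nearly <- make_engagement("u1", c(20, 20, 14, 20, 20, 20))
  expect_equal(assign_group(nearly, crit)$group, "B")
  # ineligible users are excluded
  expect_equal(assign_group(make_engagement("u1", rep(3, 7)), crit)$group,
               "excluded")
})

test_that("entry counting supports thresholds beyond a month of days", {
  expect_error(engagement_criteria(high_threshold = 60, counting_mode = "days"),
               "entries")
  crit <- engagement_criteria(high_threshold = 60, counting_mode = "entries")
  heavy <- make_engagement("u1", rep(28, 6), entries = rep(84, 6))
  expect_equal(assign_group(heavy, crit)$group, "A")
  light <- make_engagement("u2", rep(9, 6), entries = rep(30, 6))
  expect_equal(assign_group(light, crit)$group, "B")
})

test_that("groups partition users and assignment is monotone in usage", {
  crit <- engagement_criteria(high_threshold = 15)
  set.seed(11)
  recs <- dplyr::bind_rows(lapply(1:40, function(i) {
    make_engagement(sprintf("u%02d", i), sample(0:30, 7, replace = TRUE))
  }))
  g <- assign_group(recs, crit)
  expect_equal(nrow(g), 40L)
  expect_equal(anyDuplicated(g$user_id), 0L)
  expect_true(all(g$group %in% c("A", "B", "excluded")))

  bumped <- dplyr::mutate(recs,
                          logging_days = pmin(logging_days + 5L, 30L),
                          entries = pmax(entries, logging_days))
  g2 <- assign_group(bumped, crit)
  cmp <- dplyr::inner_join(g, g2, by = "user_id", suffix = c("_lo", "_hi"))
  expect_false(any(cmp$group_lo == "A" & cmp$group_hi == "B"))
})
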