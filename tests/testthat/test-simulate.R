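test_that("the same seed reproduces the cohort exactly", {
  cfg <- sim_preset("analysis1_t1dm", n_users = c(8, 6))
  a <- simulate_cohort(cfg, seed = 42)
  b <- simulate_cohort(cfg, seed = 42)
  expect_identical(a$readings, b$readings)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(cfg, seed = 43)
  expect_false(identical(a$readings, c2$readings))
})

test_that("with noise off every reading sits on the programmed trend", {
  strata <- sim_stratum("T1DM", "high", 5, "trend",
                        bg0_mean = 210, bg0_sd = 0, bg6_mean = 180,
                        reduction_sd = 0, days_min = 10, days_max = 15,
                        rpd_min = 1, rpd_max = 2)
  cfg <- sim_config(strata, reading_cv = 0, hypo_mix_prob = 0,
                    ramp = "linear", ramp_start_day = 0, ramp_end_day = 180)
  co <- simulate_cohort(cfg, seed = 2)
  joined <- dplyr::inner_join(co$readings, co$truth[, c("user_id", "start")],
                              by = "user_id")
  d <- as.numeric(difftime(joined$timestamp,
                           as.POSIXct(joined$start, tz = "UTC"),
                           units = "days"))
  expected <- 210 + (180 - 210) * pmin(d, 180) / 180
  expect_equal(joined$bg, round(expected, 2), tolerance = 1e-8)
})

test_that("presets carry the published anchors and reject unknown names", {
  p1 <- sim_preset("analysis1_t1dm")
  expect_equal(p1$strata$bg0_mean[p1$strata$archetype == "high"], 213.61)
  expect_equal(p1$strata$bg6_mean[p1$strata$archetype == "high"], 175.15)
  p2 <- sim_preset("analysis1_t2dm")
  expect_equal(p2$strata$bg0_mean[p2$strata$archetype == "low"], 232.55)
  p3 <- sim_preset("analysis2_t2dm")
  hi <- p3$strata[p3$strata$archetype == "high", ]
  expect_equal(c(hi$hbgi_q1, hi$hbgi_q2), c(9.71, 4.27))
  expect_error(sim_preset("analysis3"), "available presets")
})

test_that("raising the hypoglycemic mixture raises cohort LBGI", {
  strata <- sim_stratum("T1DM", "high", 15, "trend",
                        bg0_mean = 200, bg0_sd = 10, bg6_mean = 180,
                        days_min = 10, days_max = 15, rpd_min = 1, rpd_max = 2)
  lbgi_at <- function(p) {
    cfg <- sim_config(strata, hypo_mix_prob = p)
    co <- simulate_cohort(cfg, seed = 99)
    lbgi_hbgi(co$readings$bg)$lbgi
  }
  vals <- vapply(c(0, 0.05, 0.15), lbgi_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("programmed engagement archetypes land in their intended groups", {
  co <- simulate_cohort(sim_preset("analysis1_t1dm", n_users = c(40, 30)),
                        seed = 12)
  g <- assign_group(monthly_engagement(co$readings),
                    engagement_criteria(high_threshold = 15))
  cmp <- dplyr::inner_join(g, co$truth, by = "user_id")
  expect_gte(mean(cmp$group == cmp$intended_group), 0.99)

  co2 <- simulate_cohort(sim_preset("analysis2_t1dm", n_users = c(30, 25)),
                         seed = 13)
  g2 <- assign_group(monthly_engagement(co2$readings),
                     engagement_criteria(high_threshold = 60,
                                         counting_mode = "entries"))
  cmp2 <- dplyr::inner_join(g2, co2$truth, by = "user_id")
  expect_gte(mean(cmp2$group == cmp2$intended_group), 0.99)
})

test_that("risk-model windows realize their programmed indices", {
  co <- simulate_cohort(sim_preset("analysis2_t1dm", n_users = c(40, 30)),
                        seed = 21)
  anchors <- dplyr::transmute(
    co$truth, user_id,
    t0 = as.POSIXct(start, tz = "UTC")
  )
  windows <- dplyr::bind_rows(
    dplyr::transmute(anchors, user_id, timepoint = "t1",
                     window_start = t0, window_end = t0 + 30 * 86400),
    dplyr::transmute(anchors, user_id, timepoint = "t2",
                     window_start = t0 + 180 * 86400,
                     window_end = t0 + 210 * 86400)
  )
  s <- glycemic_summary(co$readings, windows) |>
    dplyr::inner_join(co$truth, by = "user_id")
  t1 <- dplyr::filter(s, timepoint == "t1")
  t2 <- dplyr::filter(s, timepoint == "t2")
  # composition is exact wherever an excursion was needed; the euglycemic
  # background sets a small floor for the lowest-risk users, so check the
  # upper half of each index (the half quartile selection draws from)
  hi_l <- t1$lbgi_t1 >= stats::median(t1$lbgi_t1)
  expect_lt(max(abs(t1$lbgi[hi_l] - t1$lbgi_t1[hi_l])), 0.05)
  hi_h <- t1$hbgi_t1 >= stats::median(t1$hbgi_t1)
  expect_lt(max(abs(t1$hbgi[hi_h] - t1$hbgi_t1[hi_h])), 0.05)
  hi_l2 <- t2$lbgi_t2 >= stats::median(t2$lbgi_t2)
  expect_lt(max(abs(t2$lbgi[hi_l2] - t2$lbgi_t2[hi_l2])), 0.05)
  # readings never stray outside the plausibility window
  expect_true(all(co$readings$bg > 10 & co$readings$bg < 1000))
})

test_that("impossible configurations are rejected before generation", {
  bad_days <- sim_stratum("T1DM", "high", 5, "trend", bg0_mean = 200,
                          bg0_sd = 5, bg6_mean = 180, days_min = 0)
  expect_error(sim_config(bad_days), "impossible stratum schedule")
  low_start <- sim_stratum("T1DM", "high", 5, "trend", bg0_mean = 170,
                           bg0_sd = 5, bg6_mean = 160)
  expect_error(sim_config(low_start), "183")
  no_targets <- sim_stratum("T1DM", "high", 5, "risk")
  expect_error(sim_config(no_targets), "risk strata")
  ok <- sim_stratum("T1DM", "high", 5, "trend", bg0_mean = 200,
                    bg0_sd = 5, bg6_mean = 180)
  expect_error(sim_config(ok, hypo_mix_prob = 1.2), "probabilities")
})
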