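test_that("inclusion rules exclude with machine-readable reasons", {
  spec <- cohort_spec("ea1c_reduction")
  groups <- tibble::tibble(
    user_id = sprintf("u%d", 1:7),
    group = c("A", "A", "B", "A", "excluded", "A", "A"),
    span_start = 1L
  )
  profiles <- make_profiles(sprintf("u%d", 1:6)) |>
    dplyr::mutate(
      age = c(17, 40, 40, 40, 40, 40),
      years_diagnosed = c(10, 1, 10, 10, 10, 10),
      complications = c("none", "none", "retinopathy", "none", "none", "none")
    )
  baselines <- tibble::tibble(
    user_id = sprintf("u%d", 1:7),
    baseline_bg = c(250, 250, 250, 182.9, 250, 183, NA)
  )
  res <- apply_inclusion(profiles, groups, baselines, spec)
  reasons <- setNames(res$exclusions$reason, res$exclusions$user_id)
  expect_equal(unname(reasons[c("u1", "u2", "u3", "u4", "u5", "u7")]),
               c("age", "duration", "complications", "baseline_bg",
                 "engagement", "missing_profile"))
  expect_equal(res$included$user_id, "u6") # baseline exactly 183 is included
})

test_that("percent reduction matches the published arithmetic", {
  expect_equal(round(percent_reduction(213.61, 175.15)), 18)
  expect_equal(round(percent_reduction(5.2, 3.4), 1), 34.6)
  expect_equal(percent_reduction(120, 120), 0)
  expect_lt(percent_reduction(100, 110), 0)
  expect_error(percent_reduction(0, 10), "positive")
})

test_that("paired t statistic matches its closed form and symmetry", {
  zero <- paired_t(c(5, 6, 7), c(5, 6, 7))
  expect_equal(zero$t_stat, 0)
  expect_equal(zero$p_value, 1)

  r <- paired_t(c(2, 3, 4), c(1, 1, 1)) # diffs 1, 2, 3
  expect_equal(round(r$t_stat, 3), 3.464)
  expect_equal(r$df, 2L)
  expect_equal(r$p_value, 0.0742, tolerance = 1e-3)

  fl <- paired_t(c(1, 1, 1), c(2, 3, 4))
  expect_equal(fl$t_stat, -r$t_stat)
  expect_equal(fl$p_value, r$p_value)

  deg <- paired_t(c(2, 3, 4), c(1, 2, 3)) # all diffs exactly 1
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))

  expect_error(paired_t(1:3, 1:2), "same order")
  expect_error(paired_t(c(1, NA), c(1, 2)), "complete pairs")
})

test_that("paired t agrees with the stats reference implementation", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    b <- rnorm(n, 10, 4)
    f <- b - rnorm(n, 0.5, 2)
    ours <- paired_t(b, f)
    ref <- stats::t.test(b, f, paired = TRUE)
    expect_equal(ours$t_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("top-quartile selection keeps threshold ties and small strata", {
  sel <- top_quartile(1:8)
  expect_equal(which(sel), c(7L, 8L))
  expect_equal(attr(sel, "threshold"), 6.25)

  expect_true(all(top_quartile(rep(3.3, 6))))

  sel2 <- top_quartile(c(0, 0, 0, 10))
  expect_equal(which(sel2), 4L)

  expect_warning(sel3 <- top_quartile(c(1, 9, 4)), "selecting all")
  expect_true(all(sel3))
})

test_that("an unchanged cohort yields zero reductions and p = 1", {
  strata <- dplyr::bind_rows(
    sim_stratum("T1DM", "high", 10, "trend", bg0_mean = 200, bg0_sd = 0,
                bg6_mean = 200, reduction_sd = 0,
                days_min = 15, days_max = 20, rpd_min = 1, rpd_max = 2),
    sim_stratum("T1DM", "low", 8, "trend", bg0_mean = 200, bg0_sd = 0,
                bg6_mean = 200, reduction_sd = 0,
                days_min = 6, days_max = 9, rpd_min = 1, rpd_max = 2)
  )
  cfg <- sim_config(strata, reading_cv = 0, hypo_mix_prob = 0)
  co <- simulate_cohort(cfg, seed = 5)
  expect_true(all(co$readings$bg == 200))
  a1 <- run_analysis1(co$readings, co$profiles)
  expect_true(all(abs(a1$comparisons$pct_reduction) < 1e-9))
  expect_true(all(a1$comparisons$p_value == 1))
  expect_true(all(a1$comparisons$t_stat == 0))
})

test_that("report percentages are consistent with the same report's means", {
  co <- simulate_cohort(sim_preset("analysis1_t1dm", n_users = c(25, 20)),
                        seed = 9)
  a1 <- run_analysis1(co$readings, co$profiles)
  expect_gt(nrow(a1$comparisons), 0)
  expect_equal(a1$comparisons$pct_reduction,
               percent_reduction(a1$comparisons$baseline_mean,
                                 a1$comparisons$final_mean),
               tolerance = 1e-9)
  # reported n counts the users contributing both paired timepoints
  both <- a1$estimates |>
    dplyr::filter(!is.na(baseline), !is.na(month6)) |>
    dplyr::count(diabetes_type, group)
  cmp <- dplyr::inner_join(
    dplyr::filter(a1$comparisons, metric == "bg"), both,
    by = c("diabetes_type", "group")
  )
  expect_equal(cmp$n.x, cmp$n.y)
})

test_that("risk-quartile selection depends on baseline values only", {
  # eight users, five logging days per month for seven months; month-1
  # glucose differs per user (distinct baseline LBGI ranking), later
  # months are euglycemic in variant A; variant B rewrites month 7
  base_days <- as.vector(outer(0:4, (0:6) * 30, "+"))
  mk_user <- function(i, month7_bg) {
    bg <- ifelse(base_days < 30, 100 - 5 * i,
                 ifelse(base_days >= 180, month7_bg, 112.5))
    make_readings(sprintf("u%d", i), day = base_days, bg = bg)
  }
  variant_a <- dplyr::bind_rows(lapply(1:8, mk_user, month7_bg = 112.5))
  variant_b <- dplyr::bind_rows(lapply(1:8, function(i) {
    mk_user(i, month7_bg = if (i %% 2 == 0) 55 else 130)
  }))
  profiles <- make_profiles(sprintf("u%d", 1:8))
  ra <- run_analysis2(variant_a, profiles)
  rb <- run_analysis2(variant_b, profiles)
  la <- dplyr::filter(ra$comparisons, metric == "lbgi")
  lb <- dplyr::filter(rb$comparisons, metric == "lbgi")
  # same users selected: identical baseline side, different follow-up
  expect_equal(la$quartile_threshold, lb$quartile_threshold)
  expect_equal(la$n, lb$n)
  expect_equal(la$baseline_mean, lb$baseline_mean)
  expect_false(isTRUE(all.equal(la$final_mean, lb$final_mean)))
})
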