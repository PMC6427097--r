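#' Cohort analysis specification
#'
#' Bundles the inclusion rules and stratification settings of one of the
#' two retrospective analyses:
#'
#' * `"ea1c_reduction"` — change in mean blood glucose and estimated HbA1c
#'   at baseline / month 3 / month 6, among users with an estimated
#'   baseline BG of at least `baseline_bg_min` (183 mg/dL, i.e. estimated
#'   HbA1c >= 8%). Engagement strata: >= 15 logging days/month (high) vs
#'   the rest (low).
#' * `"risk_reduction"` — change in the LBGI and HBGI risk indices between
#'   baseline (t1, analysis month 1) and month 6 (t2, analysis month 7) in
#'   the highest baseline-risk quartile of each stratum. Engagement
#'   strata: >= 60 entries/month (high) vs the rest (low).
#'
#' @param analysis `"ea1c_reduction"` or `"risk_reduction"`.
#' @param engagement An [engagement_criteria()]; defaults depend on the
#'   analysis as above.
#' @param baseline_bg_min Minimum estimated baseline BG in mg/dL
#'   (inclusive), or `NULL`. Active only for `"ea1c_reduction"`.
#' @param quartile_metrics Risk metrics for top-quartile selection. Active
#'   only for `"risk_reduction"`.
#' @param age_min Minimum age in years (inclusive; study value 18).
#' @param min_years_diagnosed Users must have lived with diabetes strictly
#'   longer than this many years (study value 1).
#' @param min_readings Minimum readings per assessment window.
#' @param window_days Analysis month length in days.
#' @param month_scheme Month convention passed to [monthly_engagement()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(analysis = c("ea1c_reduction", "risk_reduction"),
                        engagement = NULL,
                        baseline_bg_min = NULL,
                        quartile_metrics = NULL,
                        age_min = 18,
                        min_years_diagnosed = 1,
                        min_readings = 5L,
                        window_days = 30,
                        month_scheme = "rolling30") {
  analysis <- match.arg(analysis)
  if (is.null(engagement)) {
    engagement <- if (analysis == "ea1c_reduction") {
      engagement_criteria(high_threshold = 15L, counting_mode = "days")
    } else {
      engagement_criteria(high_threshold = 60L, counting_mode = "entries")
    }
  }
  if (analysis == "ea1c_reduction") {
    if (is.null(baseline_bg_min)) baseline_bg_min <- 183
    if (!is.null(quartile_metrics)) {
      abort("quartile_metrics applies only to the risk_reduction analysis")
    }
  } else {
    if (is.null(quartile_metrics)) quartile_metrics <- c("lbgi", "hbgi")
    if (!is.null(baseline_bg_min)) {
      abort("baseline_bg_min applies only to the ea1c_reduction analysis")
    }
    quartile_metrics <- match.arg(quartile_metrics, c("lbgi", "hbgi"),
                                  several.ok = TRUE)
  }
  structure(
    list(
      analysis = analysis, engagement = engagement,
      baseline_bg_min = baseline_bg_min, quartile_metrics = quartile_metrics,
      age_min = age_min, min_years_diagnosed = min_years_diagnosed,
      min_readings = as.integer(min_readings), window_days = window_days,
      month_scheme = month_scheme
    ),
    class = "cohort_spec"
  )
}

#' Apply the study inclusion rules
#'
#' Filters users on demographics (age, diabetes duration, complications),
#' engagement eligibility, and — for the glycated-hemoglobin analysis —
#' the estimated baseline blood-glucose floor. Every exclusion carries a
#' machine-readable reason code: `missing_profile`, `age`, `duration`,
#' `complications`, `engagement`, `insufficient_data`, `baseline_bg`.
#'
#' @param profiles Tibble with `user_id`, `diabetes_type`, `age`,
#'   `years_diagnosed`, `complications` (`"none"` or a description, or
#'   logical).
#' @param groups Output of [assign_group()] covering all users under study.
#' @param baselines Tibble with `user_id`, `baseline_bg` (regression
#'   estimates); required when `spec` sets `baseline_bg_min`. Users
#'   without a baseline estimate are excluded as `insufficient_data`.
#' @param spec A [cohort_spec()].
#' @return A list with `included` (tibble `user_id`, `diabetes_type`,
#'   `group`) and `exclusions` (tibble `user_id`, `reason`).
#' @export
apply_inclusion <- function(profiles, groups, baselines = NULL,
                            spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  users <- groups |>
    left_join(profiles, by = "user_id")

  no_complications <- function(x) {
    if (is.logical(x)) !x else is.na(x) | tolower(x) %in% c("none", "no", "")
  }
  users <- users |>
    mutate(reason = dplyr::case_when(
      is.na(.data$diabetes_type) ~ "missing_profile",
      .data$age < spec$age_min ~ "age",
      .data$years_diagnosed <= spec$min_years_diagnosed ~ "duration",
      !no_complications(.data$complications) ~ "complications",
      .data$group == "excluded" ~ "engagement",
      .default = NA_character_
    ))

  if (!is.null(spec$baseline_bg_min)) {
    if (is.null(baselines)) {
      abort("baseline estimates are required when baseline_bg_min is set")
    }
    users <- users |>
      left_join(baselines, by = "user_id") |>
      mutate(reason = dplyr::case_when(
        !is.na(.data$reason) ~ .data$reason,
        is.na(.data$baseline_bg) ~ "insufficient_data",
        .data$baseline_bg < spec$baseline_bg_min ~ "baseline_bg",
        .default = NA_character_
      ))
  }

  list(
    included = users |>
      filter(is.na(.data$reason)) |>
      select("user_id", "diabetes_type", "group"),
    exclusions = users |>
      filter(!is.na(.data$reason)) |>
      select("user_id", "reason")
  )
}

#' Percent reduction between two group means
#'
#' `100 * (baseline - final) / baseline`; negative when the metric
#' worsened.
#'
#' @param baseline Positive baseline value(s).
#' @param final Follow-up value(s).
#' @return Percent reduction.
#' @examples
#' percent_reduction(213.61, 175.15) # ~18
#' @export
percent_reduction <- function(baseline, final) {
  if (any(!is.finite(baseline) | baseline <= 0)) {
    abort("baseline must be positive to express a percent reduction")
  }
  100 * (baseline - final) / baseline
}

#' Paired t test on per-user values at two timepoints
#'
#' Two-sided Student's t test on the within-user differences
#' `baseline - final`, with `t = mean_diff / (sd_diff / sqrt(n))` and
#' `n - 1` degrees of freedom. When every difference is zero the result is
#' `t = 0, p = 1`; a zero-variance nonzero difference is returned with a
#' `degenerate` flag instead of a fabricated p value.
#'
#' @param baseline,final Numeric vectors of equal length (same users, same
#'   order), `n >= 2`, no missing values.
#' @return One-row tibble: `n`, `mean_diff`, `sd_diff`, `t_stat`, `df`,
#'   `p_value`, `degenerate`.
#' @examples
#' paired_t(c(2, 3, 4), c(1, 1, 1)) # diffs 1,2,3 -> t = 3.464, p ~ 0.074
#' @export
paired_t <- function(baseline, final) {
  if (length(baseline) != length(final)) {
    abort("baseline and final must pair the same users in the same order")
  }
  if (anyNA(baseline) || anyNA(final)) {
    abort("paired_t requires complete pairs; drop incomplete users first")
  }
  n <- length(baseline)
  if (n < 2L) abort("paired_t requires at least 2 pairs")
  d <- baseline - final
  md <- mean(d)
  sdd <- sd(d)
  if (sdd == 0) {
    if (md == 0) {
      return(tibble(n = n, mean_diff = 0, sd_diff = 0, t_stat = 0,
                    df = n - 1L, p_value = 1, degenerate = FALSE))
    }
    return(tibble(n = n, mean_diff = md, sd_diff = 0,
                  t_stat = sign(md) * Inf, df = n - 1L,
                  p_value = NA_real_, degenerate = TRUE))
  }
  t_stat <- md / (sdd / sqrt(n))
  tibble(n = n, mean_diff = md, sd_diff = sdd, t_stat = t_stat,
         df = n - 1L, p_value = 2 * pt(-abs(t_stat), df = n - 1),
         degenerate = FALSE)
}

#' Select the highest-risk quartile
#'
#' Returns a logical selector for the values at or above their 75th
#' percentile (linear-interpolation percentile, quantile type 7). Ties at
#' the threshold are included. With fewer than 4 values a quartile is not
#' meaningful: a warning is raised and all values are selected.
#'
#' @param x Numeric vector of baseline risk-index values (one per user in
#'   a stratum).
#' @return Logical vector the length of `x`, with the threshold attached
#'   as attribute `"threshold"`.
#' @examples
#' top_quartile(1:8) # selects 7 and 8 (75th percentile 6.25)
#' @export
top_quartile <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  if (length(x) < 4L) {
    warn(sprintf("stratum has only %d users; selecting all of them", length(x)))
    return(structure(rep(TRUE, length(x)), threshold = min(x)))
  }
  thr <- unname(quantile(x, 0.75, type = 7))
  structure(x >= thr, threshold = thr)
}

# ---- orchestration ---------------------------------------------------------

# shared front end: engagement, stratification, anchors
prepare_cohort <- function(readings, spec) {
  eng <- monthly_engagement(readings, spec$month_scheme)
  grp <- assign_group(eng, spec$engagement)
  anchors <- eng |>
    inner_join(filter(grp, .data$group != "excluded"),
               by = "user_id") |>
    filter(.data$month_index == .data$span_start) |>
    transmute(.data$user_id, anchor = .data$month_start)
  list(engagement = eng, groups = grp, anchors = anchors)
}

stratum_stats <- function(b, f) {
  tt <- paired_t(b, f)
  tibble(
    n = length(b),
    baseline_mean = mean(b), baseline_sd = sd(b),
    final_mean = mean(f), final_sd = sd(f),
    # a reduction relative to a zero baseline (possible for risk indices
    # in an all-euglycemic stratum) is undefined, not an error
    pct_reduction = if (mean(b) > 0) percent_reduction(mean(b), mean(f)) else NA_real_,
    t_stat = tt$t_stat, p_value = tt$p_value
  )
}

#' Run the estimated-HbA1c reduction analysis
#'
#' End-to-end orchestration: engagement inclusion and stratification,
#' per-user regression estimates of BG at baseline/month 3/month 6
#' (analysis months 1/4/7), the baseline-BG inclusion floor, group
#' summaries of BG and estimated HbA1c, percent reductions, and paired
#' t tests baseline vs month 3 and baseline vs month 6.
#'
#' Group summaries and the reported `n` are computed over users
#' contributing both baseline and month 6; month-3 columns are computed
#' over users contributing baseline and month 3 (`n_mid`). Users failing a
#' window's minimum reading count drop out of that timepoint only and are
#' reported in `dropped`.
#'
#' @param readings Tibble with `user_id`, `timestamp`, `bg` (mg/dL).
#' @param profiles Tibble with `user_id`, `diabetes_type` (`"T1DM"` /
#'   `"T2DM"`), `age`, `years_diagnosed`, `complications`.
#' @param spec A [cohort_spec()] with `analysis = "ea1c_reduction"`.
#' @return An object of class `glyco_analysis`: a list with `comparisons`
#'   (one row per stratum and metric, metrics `"bg"` and `"ea1c"`),
#'   `exclusions`, `dropped`, `estimates` (per-user wide table), `groups`,
#'   and `spec`.
#' @export
run_analysis1 <- function(readings, profiles,
                          spec = cohort_spec("ea1c_reduction")) {
  stopifnot(spec$analysis == "ea1c_reduction")
  parts <- prepare_cohort(readings, spec)

  traj <- bg_trajectory(
    semi_join(readings, parts$anchors, by = "user_id"),
    parts$anchors,
    window_days = spec$window_days, min_readings = spec$min_readings
  )
  est <- traj |>
    select("user_id", "timepoint", "bg_estimate") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "bg_estimate")
  baselines <- transmute(est, .data$user_id, baseline_bg = .data$baseline)

  incl <- apply_inclusion(profiles, parts$groups, baselines, spec)
  dropped <- traj |>
    semi_join(incl$included, by = "user_id") |>
    filter(.data$flagged, .data$timepoint != "baseline") |>
    transmute(.data$user_id, .data$timepoint, reason = "insufficient_data")

  dat <- incl$included |>
    inner_join(est, by = "user_id")

  one_stratum <- function(df) {
    prim <- filter(df, !is.na(.data$baseline), !is.na(.data$month6))
    mid <- filter(df, !is.na(.data$baseline), !is.na(.data$month3))
    if (nrow(prim) < 2L) return(tibble())
    bind_rows(
      bg = bind_cols(
        stratum_stats(prim$baseline, prim$month6),
        mid_stats(mid$baseline, mid$month3)
      ),
      ea1c = bind_cols(
        stratum_stats(estimate_ea1c(prim$baseline), estimate_ea1c(prim$month6)),
        mid_stats(estimate_ea1c(mid$baseline), estimate_ea1c(mid$month3))
      ),
      .id = "metric"
    )
  }
  comparisons <- dat |>
    group_by(.data$diabetes_type, .data$group) |>
    group_modify(~ one_stratum(.x)) |>
    ungroup()
  if (nrow(comparisons) > 0L) {
    comparisons <- comparisons |>
      select("diabetes_type", "group", "metric", "n", "baseline_mean",
             "baseline_sd", "n_mid", "mid_mean", "mid_sd", "final_mean",
             "final_sd", "pct_reduction", "pct_reduction_mid", "t_stat",
             "p_value", "t_stat_mid", "p_value_mid")
  }

  structure(
    list(comparisons = comparisons, exclusions = incl$exclusions,
         dropped = dropped, estimates = dat, groups = parts$groups,
         spec = spec),
    class = "glyco_analysis"
  )
}

mid_stats <- function(b, m) {
  if (length(b) < 2L) {
    return(tibble(n_mid = length(b), mid_mean = NA_real_, mid_sd = NA_real_,
                  pct_reduction_mid = NA_real_, t_stat_mid = NA_real_,
                  p_value_mid = NA_real_))
  }
  tt <- paired_t(b, m)
  tibble(n_mid = length(b), mid_mean = mean(m), mid_sd = sd(m),
         pct_reduction_mid = if (mean(b) > 0) {
           percent_reduction(mean(b), mean(m))
         } else NA_real_,
         t_stat_mid = tt$t_stat, p_value_mid = tt$p_value)
}

#' Run the hypo-/hyperglycemia risk reduction analysis
#'
#' End-to-end orchestration: engagement inclusion and stratification (high
#' engagement = 60+ entries/month), per-user LBGI and HBGI in the baseline
#' window t1 (analysis month 1) and the month-6 window t2 (analysis month
#' 7), selection of the highest baseline-risk quartile within each
#' (diabetes type, engagement group) stratum separately per metric, and a
#' paired t test t1 vs t2 on the selected users.
#'
#' Quartile selection uses t1 values only, among all included users with a
#' valid t1 window; t2 availability plays no role in selection (this keeps
#' the regression-to-the-mean structure of the design explicit). Reported
#' statistics cover selected users contributing both windows.
#'
#' @inheritParams run_analysis1
#' @param spec A [cohort_spec()] with `analysis = "risk_reduction"`.
#' @return A `glyco_analysis` list; `comparisons` has one row per stratum
#'   and risk metric with the quartile threshold attached.
#' @export
run_analysis2 <- function(readings, profiles,
                          spec = cohort_spec("risk_reduction")) {
  stopifnot(spec$analysis == "risk_reduction")
  parts <- prepare_cohort(readings, spec)

  windows <- tidyr::crossing(
    parts$anchors,
    tibble(timepoint = c("t1", "t2"), month = c(1L, 7L))
  ) |>
    mutate(
      window_start = as_utc(.data$anchor) + (.data$month - 1L) * spec$window_days * 86400,
      window_end = .data$window_start + spec$window_days * 86400
    ) |>
    select("user_id", "timepoint", "window_start", "window_end")

  summ <- glycemic_summary(
    semi_join(readings, parts$anchors, by = "user_id"),
    windows, min_readings = spec$min_readings
  )

  incl <- apply_inclusion(profiles, parts$groups, baselines = NULL, spec)
  dat <- incl$included |>
    inner_join(
      summ |>
        select("user_id", "timepoint", "lbgi", "hbgi") |>
        tidyr::pivot_wider(names_from = "timepoint",
                           values_from = c("lbgi", "hbgi")),
      by = "user_id"
    )

  one_metric <- function(df, metric) {
    v1 <- df[[paste0(metric, "_t1")]]
    v2 <- df[[paste0(metric, "_t2")]]
    has_t1 <- !is.na(v1)
    if (sum(has_t1) < 2L) return(tibble())
    sel <- top_quartile(v1[has_t1])
    chosen <- df$user_id[has_t1][sel]
    paired <- has_t1 & df$user_id %in% chosen & !is.na(v2)
    if (sum(paired) < 2L) return(tibble())
    bind_cols(
      tibble(metric = metric,
             quartile_threshold = attr(sel, "threshold"),
             n_stratum = sum(has_t1)),
      stratum_stats(v1[paired], v2[paired])
    )
  }
  comparisons <- dat |>
    group_by(.data$diabetes_type, .data$group) |>
    group_modify(function(df, key) {
      bind_rows(lapply(spec$quartile_metrics, function(m) one_metric(df, m)))
    }) |>
    ungroup()
  if (nrow(comparisons) > 0L) {
    comparisons <- comparisons |>
      select("diabetes_type", "group", "metric", "n", "n_stratum",
             "quartile_threshold", "baseline_mean", "baseline_sd",
             "final_mean", "final_sd", "pct_reduction", "t_stat", "p_value")
  }

  dropped <- incl$included |>
    anti_join(filter(summ, .data$timepoint == "t1"), by = "user_id") |>
    transmute(.data$user_id, timepoint = "t1", reason = "insufficient_data")

  structure(
    list(comparisons = comparisons, exclusions = incl$exclusions,
         dropped = dropped, estimates = dat, groups = parts$groups,
         spec = spec),
    class = "glyco_analysis"
  )
}

#' @export
print.glyco_analysis <- function(x, ...) {
  cat(sprintf("<glyco_analysis> %s\n", x$spec$analysis))
  cat(sprintf("  included users: %d; excluded: %d\n",
              nrow(x$estimates), nrow(x$exclusions)))
  print(x$comparisons, n = Inf)
  invisible(x)
}
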