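#' Synthetic SMBG cohort configuration
#'
#' Describes a cohort of simulated app users: one row of `strata` per
#' (diabetes type, engagement archetype), plus the reading-level noise
#' model and demographic sampling scheme. Two value models are available
#' per stratum:
#'
#' * `"trend"` — each user has a true daily glucose level `m(d)` that
#'   ramps from `bg0` (drawn around `bg0_mean`) to `bg6 = bg0 *
#'   (bg6_mean / bg0_mean)` between `ramp_start_day` and `ramp_end_day`
#'   and is flat afterwards. Readings are lognormal around `m(d)` with
#'   coefficient of variation `reading_cv`, replaced by a hypoglycemic
#'   component (normal around `hypo_mu`) with probability
#'   `hypo_mix_prob`. Improvements are multiplicative, so the programmed
#'   percent reduction holds for every user.
#' * `"risk"` — each user has programmed baseline LBGI/HBGI drawn from a
#'   lognormal calibrated so the *top quartile* of the stratum has the
#'   requested mean, declining multiplicatively to the programmed month-6
#'   values. Each month's readings are composed (euglycemic lognormal
#'   background plus solved low/high excursion readings) so the realized
#'   window indices equal the programmed trajectory essentially exactly.
#'   This makes parameter-recovery tests insensitive to
#'   regression-to-the-mean from quartile selection; see the methods
#'   vignette for what this does and does not emulate.
#'
#' @param strata Tibble as built by [sim_stratum()] (one row per stratum).
#' @param months Number of observation months per user (default 7).
#' @param window_days Month length in days.
#' @param reading_cv Within-day coefficient of variation of trend-model
#'   readings (default 0.15; a declared free parameter, not an estimate).
#' @param ramp `"exponential"` (fast early improvement, the shape real
#'   cohorts show) or `"linear"`.
#' @param ramp_start_day,ramp_end_day Days bracketing the improvement ramp.
#' @param ramp_tau Time constant (days) of the exponential ramp.
#' @param hypo_mix_prob,hypo_mu,hypo_sd Trend-model hypoglycemic mixture:
#'   replacement probability and the normal component's mean/sd in mg/dL.
#' @param eu_mu,eu_cv Risk-model euglycemic background level and CV.
#' @param hypo_glucose,hyper_glucose Glucose ranges (mg/dL) for composed
#'   low/high excursion readings in the risk model.
#' @param demographics Output of [default_demographics()].
#' @param start_date,start_spread_days Users' first readings are spread
#'   uniformly over this many days from `start_date`.
#' @param complication_rate Fraction of profiles marked with a diabetes
#'   complication (excluded by the study rules; default 0).
#' @param label Free-text label recorded in the config.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(strata,
                       months = 7L,
                       window_days = 30L,
                       reading_cv = 0.15,
                       ramp = c("exponential", "linear"),
                       ramp_start_day = 0,
                       ramp_end_day = 180,
                       ramp_tau = 40,
                       hypo_mix_prob = 0.01,
                       hypo_mu = 65,
                       hypo_sd = 10,
                       eu_mu = 112.5,
                       eu_cv = 0.08,
                       hypo_glucose = c(45, 65),
                       hyper_glucose = c(250, 500),
                       demographics = default_demographics("analysis1"),
                       start_date = "2017-03-01",
                       start_spread_days = 300L,
                       complication_rate = 0,
                       label = "custom") {
  ramp <- match.arg(ramp)
  stopifnot(is.data.frame(strata), nrow(strata) >= 1L)
  needed <- c("diabetes_type", "archetype", "n_users", "model",
              "days_min", "days_max", "rpd_min", "rpd_max")
  missing_cols <- setdiff(needed, names(strata))
  if (length(missing_cols)) {
    abort(paste("strata is missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (any(strata$days_min < 1 | strata$days_max > window_days |
            strata$days_min > strata$days_max |
            strata$rpd_min < 1 | strata$rpd_min > strata$rpd_max)) {
    abort("impossible stratum schedule: need 1 <= days_min <= days_max <= window_days and 1 <= rpd_min <= rpd_max")
  }
  trend <- strata$model == "trend"
  if (any(trend & (is.na(strata$bg0_mean) | is.na(strata$bg6_mean)))) {
    abort("trend strata need bg0_mean and bg6_mean")
  }
  if (any(trend & strata$bg0_mean < 183)) {
    abort("improver (trend) strata must start at a mean baseline BG of at least 183 mg/dL")
  }
  if (any(!trend & (is.na(strata$lbgi_q1) | is.na(strata$hbgi_q1)))) {
    abort("risk strata need lbgi_q1/lbgi_q2 and hbgi_q1/hbgi_q2 targets")
  }
  if (reading_cv < 0 || hypo_mix_prob < 0 || hypo_mix_prob > 1 ||
        complication_rate < 0 || complication_rate > 1) {
    abort("reading_cv must be >= 0 and probabilities must lie in [0, 1]")
  }
  if (ramp_end_day <= ramp_start_day) abort("ramp_end_day must exceed ramp_start_day")
  structure(
    list(strata = as_tibble(strata), months = as.integer(months),
         window_days = as.integer(window_days), reading_cv = reading_cv,
         ramp = ramp, ramp_start_day = ramp_start_day,
         ramp_end_day = ramp_end_day, ramp_tau = ramp_tau,
         hypo_mix_prob = hypo_mix_prob, hypo_mu = hypo_mu, hypo_sd = hypo_sd,
         eu_mu = eu_mu, eu_cv = eu_cv, hypo_glucose = hypo_glucose,
         hyper_glucose = hyper_glucose, demographics = demographics,
         start_date = as.Date(start_date),
         start_spread_days = as.integer(start_spread_days),
         complication_rate = complication_rate, label = label),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> '%s': %d strata, %d users, %d months\n",
              x$label, nrow(x$strata), sum(x$strata$n_users), x$months))
  print(x$strata)
  invisible(x)
}

#' Build one simulation stratum
#'
#' Convenience row constructor for [sim_config()]'s `strata` table.
#'
#' @param diabetes_type `"T1DM"` or `"T2DM"`.
#' @param archetype Engagement archetype label, `"high"` or `"low"`.
#' @param n_users Number of users in the stratum.
#' @param model `"trend"` or `"risk"` (see [sim_config()]).
#' @param bg0_mean,bg0_sd,bg6_mean Trend model: true baseline level
#'   distribution (mg/dL) and the programmed day-180 group mean.
#' @param reduction_sd Per-user jitter (sd, fractional) on the programmed
#'   multiplicative reduction.
#' @param lbgi_q1,lbgi_q2,hbgi_q1,hbgi_q2 Risk model: programmed
#'   top-quartile mean LBGI/HBGI at baseline (t1) and month 6 (t2).
#' @param risk_sigma Lognormal sd (log scale) of between-user baseline
#'   risk-index spread.
#' @param days_min,days_max Distinct logging days per month (uniform).
#' @param rpd_min,rpd_max Readings per logged day (uniform).
#' @return A one-row tibble.
#' @export
sim_stratum <- function(diabetes_type, archetype, n_users, model,
                        bg0_mean = NA, bg0_sd = NA, bg6_mean = NA,
                        reduction_sd = 0.03,
                        lbgi_q1 = NA, lbgi_q2 = NA,
                        hbgi_q1 = NA, hbgi_q2 = NA,
                        risk_sigma = 0.5,
                        days_min = 15, days_max = 25,
                        rpd_min = 1, rpd_max = 3) {
  tibble(
    diabetes_type = diabetes_type, archetype = archetype,
    n_users = as.integer(n_users), model = model,
    bg0_mean = bg0_mean, bg0_sd = bg0_sd, bg6_mean = bg6_mean,
    reduction_sd = reduction_sd,
    lbgi_q1 = lbgi_q1, lbgi_q2 = lbgi_q2,
    hbgi_q1 = hbgi_q1, hbgi_q2 = hbgi_q2,
    risk_sigma = risk_sigma,
    days_min = days_min, days_max = days_max,
    rpd_min = rpd_min, rpd_max = rpd_max
  )
}

#' Demographic sampling parameters
#'
#' Per-type sex ratios, age means/SDs, BMI-category and
#' diabetes-duration-bucket frequencies matching the published cohort
#' descriptions. These affect profile realism only, never the glycemic
#' metrics.
#'
#' @param which `"analysis1"` (the 211-user glycated-hemoglobin cohort) or
#'   `"analysis2"` (the 2692-user risk-index cohort).
#' @return A list used by [simulate_cohort()].
#' @export
default_demographics <- function(which = c("analysis1", "analysis2")) {
  which <- match.arg(which)
  if (which == "analysis1") {
    list(
      T1DM = list(male_p = 0.576, age_male = c(34.8, 4.22), age_female = c(31.93, 3.14)),
      T2DM = list(male_p = 0.746, age_male = c(53.2, 4.02), age_female = c(49.1, 4.11)),
      bmi_probs = c(19, 98, 74, 20) / 211,
      years_probs = c(85, 99, 27) / 211
    )
  } else {
    list(
      T1DM = list(male_p = 0.590, age_male = c(36.7, 4.98), age_female = c(31.81, 3.34)),
      T2DM = list(male_p = 0.793, age_male = c(55.2, 4.22), age_female = c(48.7, 4.41)),
      bmi_probs = c(161, 1146, 779, 606) / 2692,
      years_probs = c(1404, 1010, 278) / 2692
    )
  }
}

#' Named cohort presets
#'
#' Ready-made [sim_config()]s whose programmed group trajectories match
#' the published group-level summary statistics (see
#' [study_summary_tables()]): baseline and month-6 mean BG per stratum for
#' the glycated-hemoglobin analysis, and top-quartile baseline/month-6
#' LBGI/HBGI for the risk analysis. Default stratum sizes follow the
#' published group sizes; pass `n_users` to rescale (e.g. for
#' parameter-recovery simulations).
#'
#' @param name One of `"analysis1_t1dm"`, `"analysis1_t2dm"`,
#'   `"analysis2_t1dm"`, `"analysis2_t2dm"`.
#' @param n_users Optional per-stratum size override (scalar or length 2,
#'   high then low).
#' @return A `sim_config`.
#' @export
sim_preset <- function(name, n_users = NULL) {
  presets <- c("analysis1_t1dm", "analysis1_t2dm",
               "analysis2_t1dm", "analysis2_t2dm")
  if (!is.character(name) || length(name) != 1L || !name %in% presets) {
    abort(paste0("unknown preset '", paste(name, collapse = ","),
                 "'; available presets: ", paste(presets, collapse = ", ")))
  }
  tabs <- study_summary_tables()
  if (startsWith(name, "analysis1")) {
    type <- if (name == "analysis1_t1dm") "T1DM" else "T2DM"
    bg <- dplyr::filter(tabs$bg, .data$diabetes_type == type)
    hi <- dplyr::filter(bg, .data$group == "A")
    lo <- dplyr::filter(bg, .data$group == "B")
    n <- resolve_n(n_users, c(hi$n, lo$n))
    strata <- bind_rows(
      sim_stratum(type, "high", n[1], "trend",
                  bg0_mean = hi$baseline_mean, bg0_sd = hi$baseline_sd,
                  bg6_mean = hi$month6_mean,
                  days_min = 15, days_max = 25, rpd_min = 1, rpd_max = 3),
      sim_stratum(type, "low", n[2], "trend",
                  bg0_mean = lo$baseline_mean, bg0_sd = lo$baseline_sd,
                  bg6_mean = lo$month6_mean,
                  days_min = 6, days_max = 10, rpd_min = 1, rpd_max = 3)
    )
    sim_config(strata, demographics = default_demographics("analysis1"),
               label = name)
  } else {
    type <- if (name == "analysis2_t1dm") "T1DM" else "T2DM"
    risk <- dplyr::filter(tabs$risk, .data$diabetes_type == type)
    row_of <- function(g, m) dplyr::filter(risk, .data$group == g, .data$metric == m)
    hi_l <- row_of("A", "lbgi"); hi_h <- row_of("A", "hbgi")
    lo_l <- row_of("B", "lbgi"); lo_h <- row_of("B", "hbgi")
    n <- resolve_n(n_users, 4L * c(hi_l$n, lo_l$n))
    strata <- bind_rows(
      sim_stratum(type, "high", n[1], "risk",
                  lbgi_q1 = hi_l$baseline_mean, lbgi_q2 = hi_l$month6_mean,
                  hbgi_q1 = hi_h$baseline_mean, hbgi_q2 = hi_h$month6_mean,
                  days_min = 28, days_max = 30, rpd_min = 3, rpd_max = 4),
      sim_stratum(type, "low", n[2], "risk",
                  lbgi_q1 = lo_l$baseline_mean, lbgi_q2 = lo_l$month6_mean,
                  hbgi_q1 = lo_h$baseline_mean, hbgi_q2 = lo_h$month6_mean,
                  days_min = 8, days_max = 10, rpd_min = 3, rpd_max = 4)
    )
    # flat baseline month so the t1 window mean equals the programmed value
    sim_config(strata, ramp = "linear", ramp_start_day = 30,
               demographics = default_demographics("analysis2"),
               label = name)
  }
}

resolve_n <- function(n_users, default_n) {
  if (is.null(n_users)) return(as.integer(default_n))
  n <- as.integer(n_users)
  if (length(n) == 1L) n <- rep(n, 2L)
  stopifnot(length(n) == 2L, all(n >= 1L))
  n
}

# true trend level at fractional day d
ramp_value <- function(d, v0, v1, ramp, start, end, tau) {
  x <- pmin(pmax(d, start), end) - start
  T_len <- end - start
  w <- if (ramp == "linear") {
    1 - x / T_len
  } else {
    (exp(-x / tau) - exp(-T_len / tau)) / (1 - exp(-T_len / tau))
  }
  v1 + (v0 - v1) * w
}

# lognormal mean-log giving a prescribed top-quartile expectation
lognormal_topq_mu <- function(target_mean, sigma) {
  z75 <- qnorm(0.75)
  log(target_mean) - sigma^2 / 2 - log(pnorm(sigma - z75) / 0.25)
}

#' Simulate an SMBG cohort
#'
#' Generates per-user reading logs, demographic profiles and a
#' ground-truth table from a [sim_config()]. Regenerating with the same
#' config and seed reproduces every table exactly.
#'
#' @param config A [sim_config()] or preset name (passed to
#'   [sim_preset()]).
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `sim_cohort` with tibbles `readings`
#'   (`user_id`, `timestamp`, `bg`), `profiles` (`user_id`,
#'   `diabetes_type`, `sex`, `age`, `bmi`, `years_diagnosed`,
#'   `complications`) and `truth` (per-user programmed values: `bg0`,
#'   `bg6` for trend users; `lbgi_t1`, `lbgi_t2`, `hbgi_t1`, `hbgi_t2` for
#'   risk users; the intended group; programmed logging days per month).
#' @export
simulate_cohort <- function(config, seed = 1L) {
  if (is.character(config)) config <- sim_preset(config)
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(as.integer(seed))

  strata <- config$strata
  n_total <- sum(strata$n_users)
  users <- strata |>
    mutate(stratum = dplyr::row_number()) |>
    tidyr::uncount(.data$n_users, .remove = FALSE) |>
    mutate(user_id = sprintf("u%05d", dplyr::row_number()))

  # --- profiles -------------------------------------------------------------
  dem <- config$demographics
  sex <- character(n_total); age <- numeric(n_total)
  for (tp in unique(users$diabetes_type)) {
    i <- which(users$diabetes_type == tp)
    pars <- dem[[tp]]
    male <- runif(length(i)) < pars$male_p
    sex[i] <- ifelse(male, "male", "female")
    mu <- ifelse(male, pars$age_male[1], pars$age_female[1])
    sdv <- ifelse(male, pars$age_male[2], pars$age_female[2])
    age[i] <- pmin(pmax(rnorm(length(i), mu, sdv), 18), 85)
  }
  bmi_cat <- sample.int(4L, n_total, replace = TRUE, prob = dem$bmi_probs)
  bmi_lo <- c(16, 18.5, 25, 30)[bmi_cat]
  bmi_hi <- c(18.5, 25, 30, 40)[bmi_cat]
  yr_cat <- sample.int(3L, n_total, replace = TRUE, prob = dem$years_probs)
  yr_lo <- c(1.5, 10, 30)[yr_cat]
  yr_hi <- c(10, 30, 45)[yr_cat]
  profiles <- tibble(
    user_id = users$user_id,
    diabetes_type = users$diabetes_type,
    sex = sex,
    age = round(age, 1),
    bmi = round(runif(n_total, bmi_lo, bmi_hi), 1),
    years_diagnosed = round(runif(n_total, yr_lo, yr_hi), 1),
    complications = ifelse(runif(n_total) < config$complication_rate,
                           "present", "none")
  )

  # --- per-user programmed values -------------------------------------------
  users$start <- config$start_date +
    sample.int(config$start_spread_days, n_total, replace = TRUE) - 1L
  is_trend <- users$model == "trend"
  users$bg0 <- NA_real_; users$bg6 <- NA_real_
  if (any(is_trend)) {
    i <- which(is_trend)
    bg0 <- rnorm(length(i), users$bg0_mean[i], users$bg0_sd[i])
    bg0 <- pmax(bg0, 100) # keep the plausibility window comfortable
    ratio <- users$bg6_mean[i] / users$bg0_mean[i]
    jit <- pmin(pmax(rnorm(length(i), 0, users$reduction_sd[i]), -0.09), 0.09)
    users$bg0[i] <- bg0
    users$bg6[i] <- bg0 * ratio * (1 + jit)
  }
  users$lbgi1 <- NA_real_; users$lbgi2 <- NA_real_
  users$hbgi1 <- NA_real_; users$hbgi2 <- NA_real_
  if (any(!is_trend)) {
    i <- which(!is_trend)
    sig <- users$risk_sigma[i]
    l1 <- exp(rnorm(length(i), lognormal_topq_mu(users$lbgi_q1[i], sig), sig))
    h1 <- exp(rnorm(length(i), lognormal_topq_mu(users$hbgi_q1[i], sig), sig))
    users$lbgi1[i] <- l1
    users$lbgi2[i] <- l1 * (users$lbgi_q2[i] / users$lbgi_q1[i])
    users$hbgi1[i] <- h1
    users$hbgi2[i] <- h1 * (users$hbgi_q2[i] / users$hbgi_q1[i])
  }

  # --- logging schedule ------------------------------------------------------
  wdays <- config$window_days
  sched <- tidyr::crossing(
    users |>
      select("user_id", "stratum", "start", "model", "bg0", "bg6",
             "lbgi1", "lbgi2", "hbgi1", "hbgi2",
             "days_min", "days_max", "rpd_min", "rpd_max"),
    tibble(month = seq_len(config$months))
  ) |>
    arrange(.data$user_id, .data$month)
  sched$k_days <- sched$days_min +
    floor(runif(nrow(sched)) * (sched$days_max - sched$days_min + 1L))
  # anchor the observation clock: every user logs on day 0
  sched$force_day0 <- sched$month == 1L

  day_rows <- sched |>
    mutate(.row = dplyr::row_number())
  day_list <- lapply(seq_len(nrow(day_rows)), function(j) {
    k <- day_rows$k_days[j]
    if (day_rows$force_day0[j]) {
      c(0L, sample(seq_len(wdays - 1L), k - 1L))
    } else {
      sample(seq_len(wdays), k) - 1L
    }
  })
  days <- day_rows[rep(seq_len(nrow(day_rows)), lengths(day_list)), ] |>
    mutate(day_in_month = unlist(day_list))
  days$rpd <- days$rpd_min +
    floor(runif(nrow(days)) * (days$rpd_max - days$rpd_min + 1L))

  readings <- days[rep(seq_len(nrow(days)), days$rpd), ] |>
    mutate(
      day = (.data$month - 1L) * wdays + .data$day_in_month,
      frac = runif(dplyr::n(), 0.25, 0.96),
      d = .data$day + .data$frac
    )

  # --- reading values --------------------------------------------------------
  readings$bg <- NA_real_
  tr <- which(readings$model == "trend")
  if (length(tr)) {
    m <- ramp_value(readings$d[tr], readings$bg0[tr], readings$bg6[tr],
                    config$ramp, config$ramp_start_day, config$ramp_end_day,
                    config$ramp_tau)
    sdlog <- sqrt(log(1 + config$reading_cv^2))
    v <- m * exp(rnorm(length(tr), 0, sdlog) - sdlog^2 / 2)
    hypo <- runif(length(tr)) < config$hypo_mix_prob
    v[hypo] <- pmax(rnorm(sum(hypo), config$hypo_mu, config$hypo_sd), 40)
    readings$bg[tr] <- pmin(pmax(v, 20), 990)
  }
  rk <- which(readings$model == "risk")
  if (length(rk)) {
    readings$bg[rk] <- compose_risk_values(readings[rk, ], config)
  }

  out_readings <- readings |>
    transmute(
      .data$user_id,
      timestamp = as_utc(as.POSIXct(.data$start, tz = .gt_tz)) + .data$d * 86400,
      bg = round(.data$bg, 2)
    ) |>
    arrange(.data$user_id, .data$timestamp)

  truth <- sched |>
    group_by(.data$user_id) |>
    summarise(days_per_month = paste(.data$k_days, collapse = ";"),
              .groups = "drop") |>
    left_join(
      users |>
        transmute(.data$user_id, .data$diabetes_type,
                  intended_group = ifelse(.data$archetype == "high", "A", "B"),
                  .data$model, .data$start,
                  .data$bg0, .data$bg6,
                  lbgi_t1 = .data$lbgi1, lbgi_t2 = .data$lbgi2,
                  hbgi_t1 = .data$hbgi1, hbgi_t2 = .data$hbgi2),
      by = "user_id"
    ) |>
    select("user_id", "diabetes_type", "intended_group", "model", "start",
           "bg0", "bg6", "lbgi_t1", "lbgi_t2", "hbgi_t1", "hbgi_t2",
           "days_per_month")

  structure(
    list(readings = out_readings, profiles = profiles, truth = truth,
         config = config, seed = as.integer(seed)),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> '%s' seed %d: %d users, %d readings\n",
              x$config$label, x$seed, nrow(x$profiles), nrow(x$readings)))
  invisible(x)
}

# Compose risk-model reading values month by month so each window's
# realized mean rl / rh equals the programmed trajectory.
compose_risk_values <- function(rows, config) {
  tau <- function(v1, v2, d) {
    # programmed index level at day d (linear between ramp start/end)
    x <- pmin(pmax(d, config$ramp_start_day), config$ramp_end_day)
    v1 + (v2 - v1) * (x - config$ramp_start_day) /
      (config$ramp_end_day - config$ramp_start_day)
  }
  rl_cap <- bg_risk(max(config$hypo_glucose))$rl   # min excursion risk
  rl_max <- bg_risk(40)$rl                         # deepest allowed hypo
  rh_max <- bg_risk(700)$rh
  sdlog <- sqrt(log(1 + config$eu_cv^2))

  key <- paste(rows$user_id, rows$month)
  parts <- split(seq_len(nrow(rows)), key)
  out <- numeric(nrow(rows))
  for (idx in parts) {
    n <- length(idx)
    L_tot <- sum(tau(rows$lbgi1[idx], rows$lbgi2[idx], rows$d[idx]))
    H_tot <- sum(tau(rows$hbgi1[idx], rows$hbgi2[idx], rows$d[idx]))
    v <- config$eu_mu * exp(rnorm(n, 0, sdlog) - sdlog^2 / 2)
    r <- bg_risk(v)
    # how many excursion readings each side needs (nominal 25 / 55 risk units)
    k_l <- excursion_count(L_tot - sum(r$rl), 25, n)
    k_h <- excursion_count(H_tot - sum(r$rh), 55, n)
    while (k_l + k_h > n - 1L && (k_l > 1L || k_h > 1L)) {
      if (k_l >= k_h) k_l <- k_l - 1L else k_h <- k_h - 1L
    }
    pick <- if (k_l + k_h > 0L) sample.int(n, k_l + k_h) else integer()
    i_l <- pick[seq_len(k_l)]
    i_h <- pick[k_l + seq_len(k_h)]
    kept <- setdiff(seq_len(n), pick)
    if (k_l > 0L) {
      need <- L_tot - sum(r$rl[kept])
      if (need > 0) {
        v[i_l] <- risk_inverse(spread_risk(need, k_l, rl_max), -1)
      }
    }
    if (k_h > 0L) {
      need <- H_tot - sum(r$rh[kept])
      if (need > 0) {
        v[i_h] <- risk_inverse(spread_risk(need, k_h, rh_max), +1)
      }
    }
    out[idx] <- v
  }
  out
}

excursion_count <- function(need, nominal, n) {
  if (need <= 0) return(0L)
  min(max(1L, as.integer(ceiling(need / nominal))), max(1L, floor(0.45 * n)))
}

# split a total risk budget over k readings with a mild spread, capped
spread_risk <- function(total, k, r_max) {
  each <- total / k
  if (k == 1L || each * 1.15 > r_max) {
    return(pmin(rep(each, k), r_max))
  }
  w <- seq(0.85, 1.15, length.out = k)
  pmin(each * w / mean(w), r_max)
}
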