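#' Read and validate an SMBG readings CSV
#'
#' Expected columns: `user_id`, `timestamp` (ISO-8601), `bg_mgdl`; an
#' optional `unit` column (`"mg/dL"` / `"mmol/L"`) converts rows recorded
#' in mmol/L at ingest. Rows with unparseable timestamps, nonpositive or
#' out-of-window glucose are rejected and counted by reason; exact
#' duplicate (user, timestamp, bg) rows are dropped (app sync retries
#' plausibly duplicate records) unless `dedupe = FALSE`.
#'
#' @param path CSV file path.
#' @param bg_range Plausibility window in mg/dL; readings outside are
#'   rejected.
#' @param dedupe Drop exact duplicate rows (default TRUE).
#' @return A list with `readings` (tibble `user_id`, `timestamp`, `bg`,
#'   sorted by user then time), `rejected` (tibble of offending rows with
#'   a `reason` column: `bad_timestamp`, `nonpositive`, `out_of_range`),
#'   and `n_duplicates` (count of dropped duplicates).
#' @export
read_readings <- function(path, bg_range = c(10, 1000), dedupe = TRUE) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("user_id", "timestamp", "bg_mgdl")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    abort(paste0("readings CSV is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  has_unit <- "unit" %in% names(raw)
  parsed <- raw |>
    mutate(
      .ts = parse_iso_time(.data$timestamp),
      .bg = suppressWarnings(as.numeric(.data$bg_mgdl))
    )
  if (has_unit) {
    mmol <- !is.na(parsed$unit) & parsed$unit == "mmol/L"
    parsed$.bg[mmol] <- parsed$.bg[mmol] * 18.016
  }
  parsed <- parsed |>
    mutate(reason = dplyr::case_when(
      is.na(.data$.ts) ~ "bad_timestamp",
      is.na(.data$.bg) | .data$.bg <= 0 ~ "nonpositive",
      .data$.bg < bg_range[1] | .data$.bg > bg_range[2] ~ "out_of_range",
      .default = NA_character_
    ))
  rejected <- parsed |>
    filter(!is.na(.data$reason)) |>
    select("user_id", "timestamp", "bg_mgdl", "reason")
  good <- parsed |>
    filter(is.na(.data$reason)) |>
    transmute(.data$user_id, timestamp = .data$.ts, bg = .data$.bg)
  n_dup <- 0L
  if (dedupe) {
    before <- nrow(good)
    good <- distinct(good, .data$user_id, .data$timestamp, .data$bg)
    n_dup <- before - nrow(good)
  }
  list(
    readings = arrange(good, .data$user_id, .data$timestamp),
    rejected = rejected,
    n_duplicates = n_dup
  )
}

# ISO-8601 (date or date-time), normalized to a timezone-naive UTC clock
parse_iso_time <- function(x) {
  ts <- suppressWarnings(readr::parse_datetime(x))
  miss <- is.na(ts)
  if (any(miss)) {
    d <- suppressWarnings(readr::parse_date(x[miss], format = "%Y-%m-%d"))
    ts[miss] <- as.POSIXct(d, tz = .gt_tz)
  }
  attr(ts, "tzone") <- .gt_tz
  ts
}

#' Read a user-profile CSV
#'
#' Expected columns: `user_id`, `diabetes_type`, `sex`, `age`, `bmi`,
#' `years_diagnosed`, `complications`.
#'
#' @param path CSV file path.
#' @return A tibble with typed columns.
#' @export
read_profiles <- function(path) {
  required <- c("user_id", "diabetes_type", "sex", "age", "bmi",
                "years_diagnosed", "complications")
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  progress = FALSE))
  miss <- setdiff(required, header)
  if (length(miss)) {
    abort(paste0("profiles CSV is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  readr::read_csv(path, col_types = readr::cols(
    user_id = readr::col_character(),
    diabetes_type = readr::col_character(),
    sex = readr::col_character(),
    age = readr::col_double(),
    bmi = readr::col_double(),
    years_diagnosed = readr::col_double(),
    complications = readr::col_character()
  ), progress = FALSE)
}

#' Hash of a run configuration
#'
#' MD5 of the YAML serialization of a configuration object; recorded in
#' report file headers so outputs are traceable to the run settings.
#'
#' @param config Any serializable R object (a [cohort_spec()],
#'   [sim_config()], or plain list).
#' @return A 32-character hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf), add = TRUE)
  writeLines(yaml::as.yaml(config), tf)
  unname(tools::md5sum(tf))
}

#' Write group-comparison tables
#'
#' Writes a full-precision CSV plus a display twin whose cells use the
#' conventional `mean (SD)` formatting and rounded percent reductions
#' (nearest integer, or one decimal when `pct_digits = 1`). A comment
#' header line records the configuration hash when a config is supplied.
#'
#' @param comparisons A comparison tibble from [run_analysis1()] /
#'   [run_analysis2()].
#' @param path Output CSV path; the display twin gets a `_display.csv`
#'   suffix.
#' @param config Optional configuration recorded as a hash header.
#' @param pct_digits Digits for displayed percent reductions.
#' @return Invisibly, the paths written (character vector); nothing is
#'   written (with a warning) for an empty table.
#' @export
write_report <- function(comparisons, path, config = NULL, pct_digits = 0) {
  if (is.null(comparisons) || nrow(comparisons) == 0L) {
    warn("no comparison rows; nothing written")
    return(invisible(character()))
  }
  header <- if (!is.null(config)) {
    sprintf("# config_hash: %s", config_hash(config))
  }
  write_with_header <- function(df, p) {
    body <- readr::format_csv(df)
    writeLines(c(header, sub("\n$", "", body)), p)
  }
  write_with_header(comparisons, path)

  disp <- comparisons
  pair <- function(m, s) sprintf("%.2f (%.2f)", m, s)
  disp$baseline <- pair(disp$baseline_mean, disp$baseline_sd)
  if ("mid_mean" %in% names(disp)) {
    disp$month3 <- ifelse(is.na(disp$mid_mean), "",
                          pair(disp$mid_mean, disp$mid_sd))
  }
  disp$month6 <- pair(disp$final_mean, disp$final_sd)
  disp$reduction_pct <- formatC(round(disp$pct_reduction, pct_digits),
                                format = "f", digits = pct_digits)
  disp$t_stat <- round(disp$t_stat, 2)
  disp$p <- format_p(disp$p_value)
  keep <- intersect(
    c("diabetes_type", "group", "metric", "n", "baseline", "month3",
      "month6", "reduction_pct", "t_stat", "p"),
    names(disp)
  )
  display_path <- sub("\\.csv$", "_display.csv", path)
  write_with_header(disp[keep], display_path)
  invisible(c(path, display_path))
}

format_p <- function(p) {
  ifelse(is.na(p), "NA", ifelse(p < 0.001, "<.001",
                                sub("^0", "", sprintf("%.3f", p))))
}

#' Read a comparison table written by [write_report()]
#'
#' Skips the config-hash comment header.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_report <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Load a run configuration from YAML
#'
#' A single YAML document holding the analysis choice, engagement
#' criteria, month scheme, seed and output directory. Unspecified fields
#' fall back to the analysis defaults of [cohort_spec()].
#'
#' @param path YAML file path.
#' @return A list with elements `spec` (a [cohort_spec()]), `seed`, and
#'   `out_dir`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  analysis <- y$analysis %||% "ea1c_reduction"
  eng <- y$engagement
  criteria <- if (is.null(eng)) NULL else {
    engagement_criteria(
      min_days_per_month = eng$min_days_per_month %||% 5L,
      min_months = eng$min_months %||% 6L,
      high_threshold = eng$high_threshold %||%
        (if (analysis == "risk_reduction") 60L else 15L),
      low_range = unlist(eng$low_range %||% c(5L, 10L)),
      counting_mode = eng$counting_mode %||%
        (if (analysis == "risk_reduction") "entries" else "days"),
      strict = isTRUE(eng$strict)
    )
  }
  spec <- cohort_spec(
    analysis = analysis,
    engagement = criteria,
    baseline_bg_min = y$baseline_bg_min,
    quartile_metrics = y$quartile_metrics,
    age_min = y$age_min %||% 18,
    min_years_diagnosed = y$min_years_diagnosed %||% 1,
    min_readings = y$min_readings %||% 5L,
    window_days = y$window_days %||% 30,
    month_scheme = y$month_scheme %||% "rolling30"
  )
  list(spec = spec, seed = y$seed %||% 1L, out_dir = y$out_dir %||% ".")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
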