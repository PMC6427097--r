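#' Symmetrized blood-glucose risk decomposition
#'
#' Maps blood-glucose readings onto the symmetrized risk scale
#' `f(bg) = 1.509 * ((ln bg)^1.084 - 5.381)` (bg in mg/dL, natural log) and
#' decomposes the squared risk `10 * f^2` into a low (hypoglycemic) and a
#' high (hyperglycemic) component. The transform is calibrated so that
#' euglycemia (about 112.5 mg/dL) maps to zero risk, 20 mg/dL and
#' 600 mg/dL map to (approximately) symmetric extremes, and per-reading
#' risk grows quadratically with symmetrized deviation.
#'
#' For every reading exactly one of `rl`, `rh` is nonzero, and
#' `rl + rh == 10 * f^2`.
#'
#' @param bg Numeric vector of blood-glucose readings in mg/dL. Values must
#'   lie in the plausibility window `bg_range`.
#' @param bg_range Length-2 numeric, the admissible reading range in mg/dL.
#'   The logarithm requires positivity; meters report well below the upper
#'   default.
#' @return A tibble with one row per reading and columns `bg`, `f`
#'   (symmetrized deviation), `rl` (low risk, >= 0) and `rh` (high risk,
#'   >= 0).
#' @examples
#' bg_risk(c(50, 112.5, 400))
#' @export
bg_risk <- function(bg, bg_range = c(10, 1000)) {
  check_bg(bg, bg_range)
  f <- 1.509 * (log(bg)^1.084 - 5.381)
  risk <- 10 * f^2
  tibble(
    bg = bg,
    f  = f,
    rl = ifelse(f < 0, risk, 0),
    rh = ifelse(f > 0, risk, 0)
  )
}

check_bg <- function(bg, bg_range = c(10, 1000)) {
  if (length(bg) == 0L) {
    abort("no blood-glucose readings supplied")
  }
  bad <- !is.finite(bg) | bg < bg_range[1] | bg > bg_range[2]
  if (any(bad)) {
    abort(sprintf(
      "blood-glucose value(s) outside the plausible range [%g, %g] mg/dL: %s",
      bg_range[1], bg_range[2],
      paste(utils::head(bg[bad], 5), collapse = ", ")
    ))
  }
  invisible(bg)
}

# Inverse of the per-reading low/high risk value: the glucose level whose
# rl (side = -1) or rh (side = +1) equals `r`. Used by the synthetic
# generator to compose readings with a prescribed risk contribution.
risk_inverse <- function(r, side) {
  stopifnot(all(r >= 0), all(side %in% c(-1, 1)))
  f <- side * sqrt(r / 10)
  exp((5.381 + f / 1.509)^(1 / 1.084))
}

#' Low and high blood-glucose indices
#'
#' The LBGI and HBGI of a set of readings are the arithmetic means of the
#' per-reading low and high risk components from [bg_risk()]. They are
#' validated population proxies for hypoglycemia and hyperglycemia risk.
#'
#' @param bg Numeric vector of blood-glucose readings in mg/dL (at least
#'   one; an empty window is an error, never a silent zero).
#' @inheritParams bg_risk
#' @return A one-row tibble with columns `n`, `lbgi`, `hbgi`.
#' @examples
#' lbgi_hbgi(c(50, 400))
#' @export
lbgi_hbgi <- function(bg, bg_range = c(10, 1000)) {
  if (length(bg) == 0L) {
    abort("no readings in window: LBGI/HBGI are undefined for an empty set")
  }
  r <- bg_risk(bg, bg_range)
  tibble(n = length(bg), lbgi = mean(r$rl), hbgi = mean(r$rh))
}

#' Estimated HbA1c from mean blood glucose
#'
#' Inverts the ADAG linear relation between average glucose and HbA1c,
#' `eAG = 28.7 * A1c - 46.7` (eAG in mg/dL, A1c in %), giving
#' `eA1c = (mean_bg + 46.7) / 28.7`. 183 mg/dL corresponds to an estimated
#' HbA1c of 8%.
#'
#' @param mean_bg Numeric vector of mean blood glucose in mg/dL (positive).
#' @return Estimated HbA1c in percent.
#' @seealso [eag_from_a1c()] for the forward relation.
#' @examples
#' estimate_ea1c(183)   # 8.00
#' estimate_ea1c(213.61) # 9.07
#' @export
estimate_ea1c <- function(mean_bg) {
  if (any(!is.finite(mean_bg) | mean_bg <= 0)) {
    abort("mean blood glucose must be positive and finite")
  }
  (mean_bg + 46.7) / 28.7
}

#' Estimated average glucose from HbA1c
#'
#' The forward ADAG relation `eAG = 28.7 * A1c - 46.7`. Round-trips with
#' [estimate_ea1c()] to numerical precision.
#'
#' @param a1c Numeric vector, HbA1c in percent. Must exceed 46.7/28.7
#'   (about 1.63%) so that the implied average glucose is positive.
#' @return Estimated average glucose in mg/dL.
#' @examples
#' eag_from_a1c(8) # 183
#' @export
eag_from_a1c <- function(a1c) {
  eag <- 28.7 * a1c - 46.7
  if (any(!is.finite(eag) | eag <= 0)) {
    abort("HbA1c value implies a nonpositive average glucose; must exceed 46.7/28.7 %")
  }
  eag
}

#' Convert glucose concentrations between mg/dL and mmol/L
#'
#' Uses the molar mass convention 1 mmol/L = 18.016 mg/dL.
#'
#' @param value Numeric vector of glucose concentrations.
#' @param from,to Unit labels, one of `"mg/dL"` or `"mmol/L"`.
#' @return `value` expressed in the `to` unit.
#' @examples
#' convert_units(10, "mmol/L", "mg/dL") # 180.16
#' @export
convert_units <- function(value, from, to) {
  units <- c("mg/dL", "mmol/L")
  if (!from %in% units || !to %in% units) {
    abort(sprintf(
      "unknown glucose unit '%s'; supported units: %s",
      setdiff(c(from, to), units)[1], paste(units, collapse = ", ")
    ))
  }
  if (from == to) {
    return(value)
  }
  if (from == "mmol/L") value * 18.016 else value / 18.016
}

#' Per-user glycemic summaries over time windows
#'
#' Computes, for each user and assessment window, the reading count, mean
#' blood glucose, estimated HbA1c of the mean, and the LBGI/HBGI risk
#' indices. Windows are half-open `[window_start, window_end)`.
#'
#' @param readings A tibble with columns `user_id`, `timestamp` (POSIXct or
#'   coercible), `bg` (mg/dL).
#' @param windows A tibble with columns `user_id`, `timepoint` (label),
#'   `window_start`, `window_end`.
#' @param min_readings Windows with fewer readings are dropped (their users
#'   are reported by the calling pipeline as having insufficient data).
#' @return A tibble with one row per (user, timepoint) meeting
#'   `min_readings`: `user_id`, `timepoint`, `n_readings`, `mean_bg`,
#'   `ea1c`, `lbgi`, `hbgi`.
#' @export
glycemic_summary <- function(readings, windows, min_readings = 1L) {
  stopifnot(all(c("user_id", "timestamp", "bg") %in% names(readings)),
            all(c("user_id", "timepoint", "window_start", "window_end") %in% names(windows)))
  readings <- mutate(readings, timestamp = as_utc(.data$timestamp))
  windows <- mutate(windows,
                    window_start = as_utc(.data$window_start),
                    window_end   = as_utc(.data$window_end))
  hits <- inner_join(
    readings, windows,
    by = join_by("user_id", "timestamp" >= "window_start", "timestamp" < "window_end")
  )
  hits |>
    group_by(.data$user_id, .data$timepoint) |>
    summarise(
      n_readings = dplyr::n(),
      mean_bg = mean(.data$bg),
      lbgi = mean(bg_risk(.data$bg)$rl),
      hbgi = mean(bg_risk(.data$bg)$rh),
      .groups = "drop"
    ) |>
    mutate(ea1c = estimate_ea1c(.data$mean_bg)) |>
    filter(.data$n_readings >= min_readings) |>
    select("user_id", "timepoint", "n_readings", "mean_bg", "ea1c", "lbgi", "hbgi")
}
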