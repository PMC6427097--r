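# glycotrace

Engagement-stratified glycemic trajectory and risk-index analysis for
self-monitored blood glucose (SMBG) logs.

`glycotrace` is for biostatisticians and digital-health researchers who
evaluate diabetes-management apps retrospectively: given per-user glucose
logs and profiles, it builds monthly engagement summaries, applies the
standard inclusion rule (≥5 logging days/month sustained over ≥6
consecutive months), stratifies users into high/low-engagement groups,
estimates each user's glycemic level at baseline, month 3 and month 6,
and runs paired longitudinal comparisons of mean blood glucose, estimated
HbA1c, and the hypo-/hyperglycemia risk indices. A synthetic SMBG
generator with per-user ground truth makes every stage testable without
access to any proprietary app database.

## The statistics at the core

* **Blood-glucose risk.** Each reading (mg/dL) is symmetrized as
  `f(bg) = 1.509 * ((ln bg)^1.084 - 5.381)`; per-reading risk is `10 f²`,
  split into a low component `rl` (f < 0) and high component `rh`
  (f > 0). The **LBGI** and **HBGI** of a window are the means of `rl`
  and `rh` — validated proxies for hypoglycemia and hyperglycemia risk.
* **Estimated HbA1c.** The ADAG regression `eAG = 28.7·A1c − 46.7`
  inverted: `eA1c = (mean_bg + 46.7) / 28.7`; 183 mg/dL ≙ eA1c 8%.
* **Baseline estimation.** The BG level at baseline / month 3 / month 6
  is the OLS *intercept* over analysis months 1 / 4 / 7 (rolling 30-day
  months from the user's qualifying engagement span), with days since
  window start as predictor.
* **Risk cohorts.** Within each (diabetes type × engagement group)
  stratum, the highest baseline-risk quartile (≥ 75th percentile at t1,
  ties included) is selected and compared t1 vs t2 with a two-sided
  paired t test, `t = d̄ / (s_d/√n)`, df = n − 1.

See `vignettes/glycotrace-methods.Rmd` for assumptions, parameter
defaults, and the generator's design.

## Worked example

```r
library(glycotrace)

# a synthetic type-1 cohort programmed with the published group anchors
cohort <- simulate_cohort(sim_preset("analysis1_t1dm", n_users = c(40, 30)),
                          seed = 2024)
res <- run_analysis1(cohort$readings, cohort$profiles)
dplyr::select(dplyr::filter(res$comparisons, metric == "bg"),
              group, n, baseline_mean, final_mean, pct_reduction, p_value)
#> # A tibble: 2 × 6
#>   group     n baseline_mean final_mean pct_reduction  p_value
#>   <chr> <int>         <dbl>      <dbl>         <dbl>    <dbl>
#> 1 A        29          216.       179.          17.0 2.20e-13
#> 2 B        24          211.       176.          16.5 4.20e- 6
```

Group A (high engagement, ≥15 logging days/month) and group B fell from a
baseline around 216/211 mg/dL to about 179/176 mg/dL at month 6 — a 17%
paired reduction (the stratum was programmed with an 18% decline;
estimates carry reading noise and the 183 mg/dL baseline floor). The
exclusion log is machine-readable:

```r
dplyr::count(res$exclusions, reason)
#> # A tibble: 1 × 2
#>   reason          n
#>   <chr>       <int>
#> 1 baseline_bg    17
```

Per-reading metrics compose the same way everywhere:

```r
lbgi_hbgi(c(58, 112, 190, 340))
#> # A tibble: 1 × 3
#>       n  lbgi  hbgi
#>   <int> <dbl> <dbl>
#> 1     4  3.77  13.2
```

`run_analysis2()` is the risk-index counterpart (60+ entries/month
defines high engagement; top baseline-risk quartiles; t1 vs t2 paired
comparison). `write_report()` emits full-precision CSV tables plus
display twins in `mean (SD)` style, stamped with a config hash. A thin
command-line front end over the same functions lives at
`inst/cli/glycotrace.R` (`simulate`, `engagement`, `metrics`, `cohort`).

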