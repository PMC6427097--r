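Package: glycotrace
Title: Engagement-Stratified Glycemic Trajectories and Risk Indices from
    Self-Monitored Blood Glucose Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Retrospective analysis of self-monitored blood glucose (SMBG)
    logs exported from diabetes-management apps. Implements the symmetrized
    blood-glucose risk transform and the low/high blood glucose indices
    (LBGI/HBGI), estimated HbA1c from mean glucose via the ADAG linear
    relation, per-user app-engagement summaries with inclusion and
    stratification rules, regression-intercept estimation of glycemic level
    in monthly windows, top-quartile risk cohort selection, paired
    longitudinal comparisons, and a synthetic SMBG-log generator with
    per-user ground truth so every pipeline stage can be validated without
    access to proprietary app databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
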