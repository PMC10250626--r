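Package: t2dms
Title: Multi-State Life Table Projection of Type 2 Diabetes Burden and
    Life Expectancy by Income
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasts the burden of pharmacologically treated type 2
    diabetes (T2D) by income quintile with an irreversible illness-death
    (multi-state life table) model. Generates register-like synthetic
    longitudinal data with known ground-truth transition schedules,
    implements medication-register case ascertainment and equivalized
    income quintiles, estimates age-, gender-, income- and calendar-year
    specific transition probabilities, projects mortality and incidence
    trends to 2040, builds counterfactual obesity scenarios via the
    population attributable fraction, runs a deterministic
    cohort-component projection with a microsimulation oracle, and
    computes total life expectancy at 65 partitioned into years lived
    with and without T2D, together with income-inequality summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    mgcv,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
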