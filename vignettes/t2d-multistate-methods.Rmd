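---
title: "Multi-state projection of type 2 diabetes burden by income: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-state projection of type 2 diabetes burden by income: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dms)
```

## The model

`t2dms` projects the burden of pharmacologically treated type 2 diabetes
(T2D) with an irreversible illness–death model: every person aged 30+ is,
at the start of each calendar year, either *free of T2D*, *living with
T2D*, or *dead*. Movements between states are governed by one-year
transition probabilities specific to age (30–100), gender, income quintile
and calendar year:

* `p_inc` — probability that a disease-free person starts diabetes
  medication during the year (the register-entry, or incidence, event);
* `p_mF` — probability that a disease-free person dies during the year;
* `p_mT` — probability that a person with T2D dies during the year.

There is no recovery and no migration. A projection advances expected
(real-valued) state-occupancy counts year by year; a new cohort of
disease-free 30-year-olds enters each year. Total life expectancy at 65
and its partition into years lived with and without T2D are computed from
the same chain as period quantities.

### Conventions that had to be fixed

Several bookkeeping conventions are underdetermined by annual registry
data; the package fixes them once and tests against them:

* **Exposure-year indexing.** `p_inc` in year *t* applies to persons free
  at the start of *t*; the resulting register entry is dated *t* + 1, and
  the person counts in the T2D state from that year onward (transition at
  the year boundary). Consequently incidence is estimable only up to the
  penultimate register year, and "incidence constant at the 2019 level"
  means holding the schedule that produces 2019 register entries, i.e.
  exposure year 2018.
* **Incidence-year exposure.** Newly incident cases are not exposed to T2D
  mortality in the year of transition.
* **Terminal age.** The life table closes at age 100: both mortality
  probabilities are 1 there and incidence is 0.
* **Life-table credits.** Deaths receive half a year of person-time
  (a~x~ = 0.5); the year of an incidence transition is credited half to
  each state. These choices make the closed-form checks exact (a constant
  annual death probability *q* with no incidence gives a remaining life
  expectancy of (1 − *q*)/*q* + 0.5).
* **Population-based state mix at 65.** Life expectancy with T2D is
  computed from a starting cohort whose disease mix equals the projected
  prevalence at age 65 in that stratum-year, so it reflects onset both
  before and after 65. Expectancies are period quantities: each calendar
  year's schedule is applied at all ages.
* **Constraint repair.** Wherever a projected `p_inc + p_mF` exceeds 1,
  both are rescaled proportionally to sum to 0.999, preserving their
  ratio.

## The synthetic register

Individual-level Finnish register data cannot be redistributed, so the
package generates register-like synthetic data with a known ground-truth
transition schedule, and every estimation step is tested by parameter
recovery against that truth.

The generator simulates persons through the illness–death chain and then
writes the *observable* traces an analyst would see: annual medication
purchases (ATC codes), special-reimbursement grants, household income and
composition, and vital status. Case ascertainment then applies the
five-criteria classification (T2D-specific grant; insulin-secretion
medication; more medication years than insulin years; equal years with
first purchase at 40+; unspecified-diabetes grant at 40+) to recover the
disease state — exactly, by construction, which the test suite asserts.
Medication subtypes are drawn so that every criterion is exercised
(secretagogue users, metformin-only users, late and immediate insulin
co-users) and insulin-only purchasers emulate type 1 diabetes as negative
controls.

### What the defaults emulate

The default configuration (`default_config()`) encodes the study
conditions the synthetic world emulates; all values are per-year
probabilities unless noted:

* **Incidence age profile:** a floor of 5·10^-4^ plus a Gaussian bump of
  height 0.012 centred near age 70 (width 14 years), peaking earlier and
  higher towards the deprived quintiles (multipliers 0.80–1.26 across
  Q1–Q5, peak 1 year earlier per step) and higher in men (×1.20 vs
  ×0.85). The quintile gradient is calibrated so that the 2019 prevalence
  ratio between the most deprived and the highest income fifth is about
  1.5.
* **Calendar effects on incidence:** flat to 2006, a ×1.3
  diagnosis-campaign bump in 2007–2010, and a 1.5 %/yr multiplicative
  decline from 2011 onward. The decline magnitude is set so that
  continuing it to 2040 yields roughly 14 % fewer prevalent cases than
  holding incidence constant — the relative effect reported for the
  population this emulates.
* **Mortality:** Gompertz hazard (6·10^-4^ at age 30, log-slope 0.085/yr
  of age), men ×1.5 / women ×0.75, income gradient ×0.80–×1.20, declining
  1.5 %/yr of calendar time in both states; the T2D excess hazard ratio
  starts at 3.5 at age 30 and decays towards 1 with age (e-folding 25
  years), so the excess risk diminishes at old ages.
* **Scale:** 50,000 persons initially plus 1.6 % yearly entrants by
  default; statistical recovery checks in the test suite run at 100,000.
  These sizes keep every check within desk-scale runtimes while leaving
  enough events for the estimation layer to be meaningfully tested.

The synthetic world is *stationary* apart from the planted calendar
trends: there are no birth cohorts of varying size, no migration, no
income mobility, and no duration effect of T2D on mortality. Passing
tests therefore demonstrate that the estimation and projection machinery
is correct and internally consistent — not that the synthetic world
reproduces Finnish cohort dynamics. In particular, emergent quantities
that depend on real cohort history (for example how fast the deprived
quintile's case count grows relative to the richest) are checked only for
sign and ordering under isolating configurations.

## Estimation and projection choices

**Occurrence/exposure estimation.** Within each cell, probabilities are
event counts over at-risk counts. Cells without exposure are missing and
filled by the age smoother.

**Age smoothing.** Within each gender × quintile × year stratum, each
transition is smoothed over age on the logit scale with an
exposure-weighted binomial natural-spline regression whose basis
dimension scales with the observed event count, so sparse profiles get a
near-linear logit fit instead of an oscillating one. An empirical-logit
transform with a half-count continuity correction was rejected: with
rare events and cells of ~100 persons it inflates smoothed incidence by
tens of percent, which the recovery tests against the planted schedule
expose immediately. Cells observed with at least 500 at-risk persons keep
their raw estimate; outside the observed age span the boundary value is
held constant rather than extrapolated on the logit scale, which data
cannot support. A fully missing age profile is an error.

**Mortality trend projection.** Calendar trends are fit on the log scale
to the *disease-free* mortality series and extrapolated log-linearly from
the last fitted year; projected `p_mF` and `p_mT` are the anchor-year age
profiles scaled by the common trend factor, which freezes the T2D:non-T2D
ratio and all income differentials at their end-of-history levels. Two
statistical points drove this design:

1. *Age adjustment.* Trend models carry single-age levels inside each
   band because the age composition of a 10-year band drifts over 24
   calendar years; fitting band-aggregated rates without age adjustment
   biased recovered slopes toward zero.
2. *Fitting the disease-free series.* Total mortality mixes two states
   whose population shares shift over time; because the T2D share rises
   and T2D mortality is higher, the total-mortality slope underestimates
   the common decline. With the differential frozen, one trend drives
   both states, and the disease-free series estimates it without that
   confound.

**Slope pooling.** By default the calendar slope is shared per gender
(with fully stratum-specific anchor levels), for both mortality and
incidence; per-band and global pooling are available. The package takes
this position deliberately: a 22-year extrapolation multiplies any slope
error by exp(22·Δb), and at desk scale the stratum-level slope standard
errors (~0.005–0.05 on the log scale) would make stratum-specific
extrapolations noise-dominated — the incidence window after excluding the
2007–2010 diagnosis-campaign years contains only eight annual points.
Pooling the slope while keeping stratum-specific levels preserves every
cross-sectional differential, consistent with the frozen-differential
assumption of the mortality projection.

**Scenarios.** The baseline holds incidence at its last estimable level;
scenario A projects the post-2011 declining trend (the 2007–2010 bump
years are never used for fitting; a fitted *rising* trend is allowed but
warned about); scenarios B and C multiply scenario A's future `p_inc` and
`p_mT` by 1 − PAF and 1 + PAF respectively, with the population
attributable fraction of obesity computed by Levin's formula
p(RR − 1)/(1 + p(RR − 1)) per gender, separately for incidence and for
T2D mortality. The shipped obesity inputs (prevalence 0.25, RR 3.0 for
incidence, RR 1.5 for T2D mortality) are *illustrative placeholders* —
no authoritative values are bundled — and every output that depends on
them says so via the PAF table carried alongside.

**Engine.** The deterministic engine advances expected counts (a
cohort-component multi-state life table); a stochastic microsimulation
with the same probabilities serves as an independent oracle, and the test
suite requires agreement within three Monte-Carlo standard errors at
100,000 agents. Conservation of persons (occupancy gains = entrants −
deaths, exactly) is asserted at every step.

## Numerical and degenerate-input behaviour

* Probabilities are clamped to [10^-8^, 1 − 10^-8^] after trend
  extrapolation; scenario multipliers clamp to [0, 1] and log how many
  cells they clamped.
* Income ties in quintile assignment break by stable person identifier
  order, making the assignment deterministic; stratum group sizes never
  differ by more than one.
* A failed smooth trend fit falls back to a log-linear fit on aggregated
  rates, with a message.
* All randomness flows from the single configuration seed; the pipeline
  is byte-reproducible given the seed, which the manifest (config hash,
  seed, package version) records.

## Known limitations

* The synthetic register has no income mobility (quintile fixed at cohort
  entry), no household dynamics beyond the equivalence-scale arithmetic,
  no T2D-duration effect on mortality, and a stationary age structure —
  so absolute projected magnitudes are properties of the synthetic world,
  not of any real population.
* Period life expectancies condition on a single calendar year's
  schedule; cohort interpretations are not supported.
* Trend recovery at a 22-year horizon is noise-limited for incidence even
  at 100,000 persons: with ~8 fit years the pooled slope standard error
  (~0.01) corresponds to a ±20–25 % band on the 2040 level. The test
  suite states the 5 % recovery property and reports its status honestly
  rather than relaxing it; mortality recovery, with 24 fit years and an
  order of magnitude more events, sits comfortably within 5 %.
* No uncertainty intervals are produced for projections.

## A worked example

```{r example, eval = FALSE}
cfg <- default_config(seed = 1)
cfg$n_persons <- 20000L   # desk-scale demonstration
res <- run_pipeline(cfg, scenarios = c("baseline", "A"))

res$prevalence$baseline       # prevalent cases by quintile, 2020/2030/2040
res$health_expectancy$baseline  # TLE/LE with/without T2D at 65
res$inequality$baseline       # Q5 - Q1 gaps
res$validation$prevalence     # ascertainment fidelity vs ground truth
```

The same pipeline, at 100,000 persons and with all four scenarios, is
what `scripts/acceptance.R` runs to produce the package's headline
numbers.
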