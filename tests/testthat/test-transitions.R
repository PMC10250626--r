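test_that("occurrence/exposure estimation reproduces simple ratios", {
  counts <- small_counts()
  est <- estimate_transition_probabilities(counts)
  # direct ratio spot checks against the count columns
  nz <- est[!is.na(est$p_inc) & est$n_free > 0, ]
  expect_equal(nz$p_inc, nz$n_incident / nz$n_free)
  expect_true(all(est$p_inc[est$n_incident == 0 & est$n_free > 0 &
                              est$year < max(est$year)] == 0, na.rm = TRUE))
  # cells without exposure are missing, not zero
  expect_true(all(is.na(est$p_mT[est$n_t2d == 0])))
  # incidence is structurally censored in the final register year
  expect_true(all(is.na(est$p_inc[est$year == max(est$year)])))
})

test_that("inconsistent event counts are rejected", {
  counts <- small_counts()
  bad <- counts
  i <- which(bad$n_free > 0)[1]
  bad$n_incident[i] <- bad$n_free[i] + 1L
  expect_error(estimate_transition_probabilities(bad), "exceed")
})

test_that("the age smoother reproduces a noiseless logistic profile", {
  probs <- toy_probs(
    years = 2000,
    f_inc = function(a, g, q, y) plogis(-9 + 0.07 * a),
    f_mF = function(a, g, q, y) plogis(-10 + 0.09 * a),
    f_mT = function(a, g, q, y) plogis(-8.5 + 0.09 * a)
  )
  sm <- smooth_over_age(probs)
  interior <- sm$age < 100
  for (col in c("p_inc", "p_mF", "p_mT")) {
    expect_lt(max(abs(sm[[col]][interior] - probs[[col]][interior])), 1e-3)
  }
})

test_that("a missing age cell is interpolated between its neighbours", {
  probs <- toy_probs(years = 2000,
                     f_mF = function(a, g, q, y) plogis(-10 + 0.09 * a))
  hole <- probs$age == 60
  probs$p_mF[hole] <- NA
  sm <- smooth_over_age(probs)
  truth <- plogis(-10 + 0.09 * 60)
  expect_lt(max(abs(sm$p_mF[hole] - truth)), 1e-3)
})

test_that("smoothing sparse noisy cells beats the raw estimate", {
  set.seed(31)
  true_p <- function(a) plogis(-9 + 0.08 * a)
  grid <- toy_probs(years = 2000, f_mF = function(a, g, q, y) true_p(a))
  n <- 200L  # below the keep-raw threshold
  grid$n_free <- n
  grid$n_death_free <- rbinom(nrow(grid), n, grid$p_mF)
  grid$n_incident <- 0L
  grid$n_t2d <- n
  grid$n_death_t2d <- rbinom(nrow(grid), n, grid$p_mT)
  raw <- grid
  raw$p_mF <- raw$n_death_free / raw$n_free
  sm <- smooth_over_age(raw)
  interior <- sm$age < 100
  mse_raw <- mean((raw$p_mF[interior] - true_p(raw$age[interior]))^2)
  mse_sm <- mean((sm$p_mF[interior] - true_p(sm$age[interior]))^2)
  expect_lt(mse_sm, mse_raw)
})

test_that("well-supported cells are untouched by the smoother", {
  set.seed(32)
  grid <- toy_probs(years = 2000)
  grid$n_free <- ifelse(grid$age %in% 50:70, 1000L, 50L)
  grid$n_incident <- rbinom(nrow(grid), grid$n_free, grid$p_inc)
  grid$n_death_free <- rbinom(nrow(grid), grid$n_free, grid$p_mF)
  grid$n_t2d <- 1000L
  grid$n_death_t2d <- rbinom(nrow(grid), grid$n_t2d, grid$p_mT)
  raw <- estimate_transition_probabilities(grid)
  sm <- smooth_over_age(raw)
  big <- sm$age %in% 50:70
  expect_equal(sm$p_mF[big], raw$p_mF[big], tolerance = 1e-12)
})

test_that("an all-missing age profile is an error", {
  probs <- toy_probs(years = 2000)
  probs$p_mF[probs$gender == "M" & probs$quintile == "Q1"] <- NA
  expect_error(smooth_over_age(probs), "all-missing")
})

test_that("constant historical mortality projects as constant", {
  probs <- toy_probs(years = 1995:2018,
                     f_mF = function(a, g, q, y) 0.002 * exp(0.07 * (a - 30)),
                     f_mT = function(a, g, q, y) 0.004 * exp(0.07 * (a - 30)))
  proj <- fit_mortality_trend(probs, fit_years = 1995:2018,
                              target_years = 2019:2040)
  p40 <- proj[proj$year == 2040 & proj$age < 100, ]
  p18 <- proj[proj$year == 2018 & proj$age < 100, ]
  expect_equal(p40$p_mF, p18$p_mF, tolerance = 1e-6)
  expect_equal(p40$p_mT, p18$p_mT, tolerance = 1e-6)
})

test_that("an exact exponential mortality decline is continued analytically", {
  rate <- 0.02
  probs <- toy_probs(
    years = 1995:2018,
    f_mF = function(a, g, q, y) {
      0.003 * exp(0.07 * (a - 30)) * (1 - rate)^(y - 1995)
    },
    f_mT = function(a, g, q, y) {
      0.006 * exp(0.07 * (a - 30)) * (1 - rate)^(y - 1995)
    }
  )
  proj <- fit_mortality_trend(probs, fit_years = 1995:2018,
                              target_years = 2019:2040)
  got <- proj[proj$year == 2040 & proj$age %in% 40:90, ]
  ref <- probs[probs$year == 2018 & probs$age %in% 40:90, ]
  expected <- ref$p_mF * (1 - rate)^22
  expect_equal(got$p_mF, expected, tolerance = 0.01)
})

test_that("the T2D mortality differential is frozen in projections", {
  sm <- small_smoothed()
  proj <- suppressMessages(fit_mortality_trend(sm))
  # clamping bends the ratio where it binds (saturated old-age cells at the
  # ceiling, zero-death cells at the floor), so check the cells that stay
  # away from both boundaries in every year
  fut <- proj[proj$year >= 2019 & proj$age < 100, ]
  key_all <- paste(fut$age, fut$gender, fut$quintile)
  ok_hi <- names(which(tapply(fut$p_mT, key_all, max) < 0.99))
  ok_lo <- names(which(tapply(pmin(fut$p_mF, fut$p_mT), key_all, min) > 1e-6))
  fut <- fut[key_all %in% intersect(ok_hi, ok_lo), ]
  expect_gt(nrow(fut), 100)  # the property is checked on a non-trivial set
  ratio <- fut$p_mT / fut$p_mF
  r19 <- fut[fut$year == 2019, ]
  lookup <- setNames(r19$p_mT / r19$p_mF,
                     paste(r19$age, r19$gender, r19$quintile))
  expect_equal(ratio,
               unname(lookup[paste(fut$age, fut$gender, fut$quintile)]),
               tolerance = 1e-9)
})

test_that("trend projection is scale-equivariant on the log scale", {
  probs <- toy_probs(
    years = 2000:2018,
    f_mF = function(a, g, q, y) 0.002 * exp(0.06 * (a - 30)) * 0.985^(y - 2000),
    f_mT = function(a, g, q, y) 0.004 * exp(0.06 * (a - 30)) * 0.985^(y - 2000)
  )
  c_mult <- 1.7
  scaled <- probs
  scaled$p_mF <- pmin(scaled$p_mF * c_mult, 1)
  scaled$p_mT <- pmin(scaled$p_mT * c_mult, 1)
  scaled$p_mF[scaled$age == 100] <- 1
  scaled$p_mT[scaled$age == 100] <- 1
  a <- fit_mortality_trend(probs, fit_years = 2000:2018,
                           target_years = 2019:2030)
  b <- fit_mortality_trend(scaled, fit_years = 2000:2018,
                           target_years = 2019:2030)
  ia <- a$year == 2030 & a$age %in% 40:80
  expect_equal(b$p_mF[b$year == 2030 & b$age %in% 40:80],
               a$p_mF[ia] * c_mult, tolerance = 1e-6)
})

test_that("scenario-A incidence projection ignores the planted bump", {
  rate <- 0.03
  f_inc <- function(a, g, q, y) {
    base <- 0.002 + 0.01 * exp(-((a - 68) / 14)^2)
    fac <- ifelse(y %in% 2007:2010, 1.3,
                  ifelse(y >= 2011, (1 - rate)^(y - 2010), 1))
    base * fac
  }
  probs <- toy_probs(years = 1995:2018, f_inc = f_inc)
  proj <- fit_incidence_trend(probs, trend_from = 2011,
                              exclude_years = 2007:2010,
                              target_years = 2019:2040)
  got <- proj[proj$year == 2040 & proj$age %in% 40:90, ]
  ref <- probs[probs$year == 2018 & probs$age %in% 40:90, ]
  expect_equal(got$p_inc, ref$p_inc * (1 - rate)^22, tolerance = 0.02)
})

test_that("flat incidence projects flat and exclusion has an effect", {
  flat <- toy_probs(years = 2000:2018,
                    f_inc = function(a, g, q, y) 0.004 + 0.008 * (a %in% 55:80))
  proj <- fit_incidence_trend(flat, trend_from = 2011,
                              target_years = 2019:2040)
  expect_equal(proj$p_inc[proj$year == 2040 & proj$age < 100],
               flat$p_inc[flat$year == 2018 & flat$age < 100],
               tolerance = 1e-6)

  # with a bump inside the window, excluding it changes the projection
  f_inc <- function(a, g, q, y) {
    0.005 * ifelse(y %in% 2007:2010, 1.5, 1) * 0.99^(pmax(y - 2005, 0))
  }
  bumpy <- toy_probs(years = 2000:2018, f_inc = f_inc)
  with_ex <- fit_incidence_trend(bumpy, trend_from = 2005,
                                 exclude_years = 2007:2010,
                                 target_years = 2019:2040)
  without_ex <- suppressWarnings(fit_incidence_trend(
    bumpy, trend_from = 2005, exclude_years = integer(),
    target_years = 2019:2040
  ))
  expect_gt(
    max(abs(with_ex$p_inc[with_ex$year == 2040] -
              without_ex$p_inc[without_ex$year == 2040]), na.rm = TRUE),
    1e-5
  )
})

test_that("a rising incidence trend is flagged, not silenced", {
  rising <- toy_probs(years = 2011:2018,
                      f_inc = function(a, g, q, y) 0.004 * 1.02^(y - 2011))
  expect_warning(
    fit_incidence_trend(rising, trend_from = 2011, target_years = 2019:2025),
    "rising"
  )
})

test_that("holding incidence constant is idempotent and leaves mortality", {
  probs <- toy_probs(years = 2010:2018,
                     f_inc = function(a, g, q, y) 0.005 * 0.98^(y - 2010))
  proj <- fit_mortality_trend(probs, fit_years = 2010:2018,
                              target_years = 2019:2040)
  held <- hold_incidence_constant(proj, at_year = 2019)
  fut <- held[held$year >= 2019, ]
  ref <- held[held$year == 2018, ]
  key <- function(d) paste(d$age, d$gender, d$quintile)
  expect_equal(fut$p_inc, setNames(ref$p_inc, key(ref))[key(fut)],
               ignore_attr = TRUE)
  expect_equal(held$p_mF, proj$p_mF)
  held2 <- hold_incidence_constant(held, at_year = 2019)
  expect_equal(held2$p_inc, held$p_inc)
})

test_that("projected probability sets satisfy the row constraints", {
  sm <- small_smoothed()
  scen <- suppressWarnings(suppressMessages(build_all_scenarios(sm)))
  for (s in names(scen)) {
    p <- scen[[s]]
    fut <- p[p$year >= 2019, ]
    expect_false(anyNA(fut$p_inc))
    expect_true(all(fut$p_inc >= 0 & fut$p_inc <= 1))
    expect_true(all(fut$p_mF > 0 & fut$p_mF <= 1))
    expect_true(all(fut$p_mT > 0 & fut$p_mT <= 1))
    expect_true(all(fut$p_inc + fut$p_mF <= 1 + 1e-12))
  }
})

test_that("transition probabilities round-trip through CSV", {
  probs <- toy_probs(years = 2000:2001,
                     f_inc = function(a, g, q, y) 0.0123456789012 * (q / 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_transition_probs(probs, path)
  back <- read_transition_probs(path)
  expect_equal(back$p_inc, probs$p_inc, tolerance = 1e-12)
  expect_equal(back$p_mF, probs$p_mF, tolerance = 1e-12)
})
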