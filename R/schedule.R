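#' Ground-truth transition schedule of the synthetic register
#'
#' Builds the annual transition probabilities that drive the generator:
#' `p_inc` = P(free -> T2D), `p_mF` = P(free -> dead), `p_mT` = P(T2D -> dead),
#' on the full age x gender x quintile x year grid. Probability years are
#' exposure years: a person free at the start of year t transitions during t
#' and enters the register (medication start) in year t + 1.
#'
#' The schedule encodes the planted features the estimation layer is tested
#' against: a unimodal incidence age profile peaking after 60 (earlier and
#' higher towards Q5, higher in men), a multiplicative incidence bump in the
#' configured bump years and a constant multiplicative decline from
#' `decline_from` onwards, Gompertz background mortality with an income
#' gradient and a secular decline shared by both states, and a T2D excess
#' hazard that diminishes with age. At the terminal age (100) both mortality
#' probabilities are 1 and incidence is 0, closing the life table.
#'
#' Extending `years` beyond the observation window yields the analytic
#' continuation of the planted trends, which serves as the oracle for
#' trend-projection recovery tests.
#'
#' @param config Configuration list, see [default_config()].
#' @param years Calendar years to tabulate; defaults to the observation
#'   window through the projection horizon.
#' @return A tibble (age, gender, quintile, year, p_inc, p_mF, p_mT).
#' @export
truth_schedule <- function(config = default_config(), years = NULL) {
  years <- years %||% seq(config$years[1], config$horizon)
  inc <- config$incidence
  mort <- config$mortality
  grid <- expand_grid(
    age = AGE_MIN:AGE_MAX, gender = GENDERS, quintile = QUINTILES, year = years
  )
  q <- quintile_index(grid$quintile)
  male <- grid$gender == "M"

  peak_age <- inc$peak_age + inc$quintile_peak_shift * (q - 1)
  shape <- inc$base + inc$peak * exp(-((grid$age - peak_age) / inc$peak_width)^2)
  p_inc <- shape *
    ifelse(male, inc$male_mult, inc$female_mult) *
    inc$quintile_mult[q] *
    incidence_year_factor(grid$year, inc)

  h_free <- mort$gompertz_a * exp(mort$gompertz_b * (grid$age - AGE_MIN)) *
    ifelse(male, mort$male_mult, mort$female_mult) *
    mort$quintile_mult[q] *
    (1 - mort$decline_rate)^(grid$year - config$years[1])
  hr <- 1 + mort$t2d_hr_base * exp(-(grid$age - AGE_MIN) / mort$t2d_hr_decay)
  p_mF <- 1 - exp(-h_free)
  p_mT <- 1 - exp(-h_free * hr)

  terminal <- grid$age == AGE_MAX
  p_inc[terminal] <- 0
  p_mF[terminal] <- 1
  p_mT[terminal] <- 1

  out <- grid
  out$p_inc <- clamp(p_inc, 0, 1)
  out$p_mF <- clamp(p_mF, 0, 1)
  out$p_mT <- clamp(p_mT, 0, 1)
  bad <- out$p_inc + out$p_mF > 1
  if (any(bad)) abort("invalid schedule: p_inc + p_mF > 1 in some stratum")
  class(out) <- c("transition_probs", class(out))
  out
}

# calendar-year multiplier on incidence: flat, then bump, then steady decline
incidence_year_factor <- function(year, inc) {
  f <- rep(1, length(year))
  f[year %in% inc$bump_years] <- inc$bump_height
  declining <- year >= inc$decline_from
  f[declining] <- (1 - inc$decline_rate)^(year[declining] - inc$decline_from + 1)
  f
}

# probabilities as [age, gender, quintile, year] arrays for fast lookup
probs_arrays <- function(probs) {
  years <- sort(unique(probs$year))
  dims <- c(AGE_MAX - AGE_MIN + 1L, 2L, 5L, length(years))
  idx <- cbind(
    probs$age - AGE_MIN + 1L,
    match(probs$gender, GENDERS),
    quintile_index(probs$quintile),
    match(probs$year, years)
  )
  mk <- function(v) {
    a <- array(NA_real_, dims)
    a[idx] <- v
    a
  }
  list(
    years = years,
    p_inc = mk(probs$p_inc),
    p_mF = mk(probs$p_mF),
    p_mT = mk(probs$p_mT)
  )
}

# steady-state prevalence of T2D by age under a single year's schedule,
# used to seed the initial population of the generator
steady_state_prevalence <- function(probs_year) {
  arr <- probs_arrays(probs_year)
  n_age <- AGE_MAX - AGE_MIN + 1L
  prev <- array(0, c(n_age, 2L, 5L))
  for (g in 1:2) {
    for (q in 1:5) {
      s_free <- 1
      s_t2d <- 0
      for (a in seq_len(n_age)) {
        alive <- s_free + s_t2d
        prev[a, g, q] <- if (alive > 0) s_t2d / alive else 0
        pf <- arr$p_mF[a, g, q, 1]
        pi <- arr$p_inc[a, g, q, 1]
        pt <- arr$p_mT[a, g, q, 1]
        new_t2d <- s_free * pi
        s_free <- s_free * (1 - pf - pi)
        s_t2d <- s_t2d * (1 - pt) + new_t2d
      }
    }
  }
  prev
}
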