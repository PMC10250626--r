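#' Period life expectancy partitioned by disease state
#'
#' Runs a synthetic period cohort from `from_age` through the illness-death
#' chain under a single calendar year's transition schedule (the same update
#' rule as [step_population()]) and accumulates person-years by state.
#' Conventions: half-year credit in the year of death (a_x = 0.5), and the
#' year of a free-to-T2D transition is credited half to each state. The
#' starting cohort is split between the disease-free and T2D states by
#' `state_mix`, so life expectancy with T2D reflects both onset before
#' `from_age` and later incidence.
#'
#' The exact partition `le_without + le_with = tle` holds by construction.
#'
#' @param probs_year One gender x quintile stratum of one calendar year of a
#'   `transition_probs` set, covering all ages `from_age` to 100.
#' @param state_mix Length-2 vector (share disease-free, share with T2D) at
#'   `from_age`; normalized to sum to 1.
#' @param from_age Starting age (default 65).
#' @return Named numeric vector: `tle`, `le_without`, `le_with` (years per
#'   starting person).
#' @export
state_life_expectancy <- function(probs_year, state_mix = c(1, 0),
                                  from_age = 65) {
  ages <- from_age:AGE_MAX
  df <- probs_year |>
    filter(.data$age %in% ages) |>
    arrange(.data$age)
  if (!identical(as.integer(df$age), as.integer(ages))) {
    abort("probabilities missing for some ages between from_age and 100")
  }
  if (any(is.na(df$p_inc) | is.na(df$p_mF) | is.na(df$p_mT))) {
    abort("transition probabilities contain NA over the life-table ages")
  }
  if (any(df$p_inc + df$p_mF > 1 + 1e-9)) {
    abort("p_inc + p_mF must not exceed 1 at any age")
  }
  if (sum(state_mix) <= 0) abort("state_mix must have positive mass")
  l_f <- state_mix[1] / sum(state_mix)
  l_t <- state_mix[2] / sum(state_mix)

  le_without <- 0
  le_with <- 0
  for (i in seq_along(ages)) {
    d_f <- l_f * df$p_mF[i]
    inc <- l_f * df$p_inc[i]
    d_t <- l_t * df$p_mT[i]
    le_without <- le_without + (l_f - d_f - inc) + 0.5 * d_f + 0.5 * inc
    le_with <- le_with + (l_t - d_t) + 0.5 * d_t + 0.5 * inc
    l_f <- l_f - d_f - inc
    l_t <- l_t - d_t + inc
  }
  c(tle = le_without + le_with, le_without = le_without, le_with = le_with)
}

#' Health expectancy table at 65 by gender, quintile and year
#'
#' For each requested calendar year and stratum, computes total life
#' expectancy at 65 and its partition into years lived with and without
#' T2D, using that year's period transition schedule and the projected
#' prevalence mix at age 65 from the trajectory as the starting state mix.
#'
#' @param trajectory A `population_trajectory` covering `years`.
#' @param probs The scenario `transition_probs` set covering `years` at all
#'   ages 65-100.
#' @param years Calendar years to evaluate.
#' @param from_age Starting age of the life table (default 65).
#' @return Tibble (gender, quintile, year, tle, le_without, le_with,
#'   prop_without) where `prop_without = le_without / tle`.
#' @export
health_expectancy_table <- function(trajectory, probs, years = c(2020, 2040),
                                    from_age = 65) {
  missing_years <- setdiff(years, unique(trajectory$year))
  if (length(missing_years)) {
    abort(paste0("trajectory does not cover year(s) ",
                 paste(missing_years, collapse = ", ")))
  }
  grid <- expand_grid(gender = GENDERS, quintile = QUINTILES, year = years)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$gender[i]; q <- grid$quintile[i]; y <- grid$year[i]
    mix_row <- trajectory |>
      filter(.data$year == y, .data$age == from_age,
             .data$gender == g, .data$quintile == q)
    if (nrow(mix_row) == 0 || mix_row$n_free + mix_row$n_t2d <= 0) {
      abort(paste0("no population at age ", from_age, " in ", g, "/", q,
                   "/", y, " to anchor the state mix"))
    }
    p_year <- probs |>
      filter(.data$year == y, .data$gender == g, .data$quintile == q)
    le <- state_life_expectancy(p_year, c(mix_row$n_free, mix_row$n_t2d),
                                from_age = from_age)
    tibble(gender = g, quintile = q, year = y,
           tle = le[["tle"]], le_without = le[["le_without"]],
           le_with = le[["le_with"]],
           prop_without = le[["le_without"]] / le[["tle"]])
  })
  bind_rows(rows)
}

HE_MEASURES <- c("tle", "le_without", "le_with", "prop_without")

#' Income-gap summary of a health expectancy table
#'
#' Absolute and percentage gaps between the most deprived (Q5) and highest
#' income (Q1) quintiles, per gender, year and measure; the percentage gap
#' is relative to the Q1 value.
#'
#' @param het Output of [health_expectancy_table()] (or any tibble with the
#'   same columns, e.g. published values).
#' @return Tibble (gender, year, measure, q1, q5, gap, gap_pct).
#' @export
inequality_summary <- function(het) {
  if (!all(c("Q1", "Q5") %in% het$quintile)) {
    abort("both Q1 and Q5 must be present")
  }
  het |>
    filter(.data$quintile %in% c("Q1", "Q5")) |>
    pivot_longer(all_of(intersect(HE_MEASURES, names(het))),
                 names_to = "measure", values_to = "value") |>
    pivot_wider(id_cols = c("gender", "year", "measure"),
                names_from = "quintile", values_from = "value") |>
    mutate(
      gap = .data$Q5 - .data$Q1,
      gap_pct = .data$gap / .data$Q1 * 100
    ) |>
    rename(q1 = "Q1", q5 = "Q5")
}

#' Change in health expectancy between two calendar years
#'
#' @param het Output of [health_expectancy_table()] covering both years.
#' @param from,to Calendar years to compare.
#' @return Tibble (gender, quintile, measure, value_from, value_to, diff,
#'   pct) with `pct = diff / value_from * 100`.
#' @export
health_expectancy_changes <- function(het, from = min(het$year),
                                      to = max(het$year)) {
  long <- het |>
    filter(.data$year %in% c(from, to)) |>
    pivot_longer(all_of(intersect(HE_MEASURES, names(het))),
                 names_to = "measure", values_to = "value") |>
    pivot_wider(id_cols = c("gender", "quintile", "measure"),
                names_from = "year", values_from = "value")
  long |>
    mutate(
      value_from = .data[[as.character(from)]],
      value_to = .data[[as.character(to)]],
      diff = .data$value_to - .data$value_from,
      pct = .data$diff / .data$value_from * 100
    ) |>
    select("gender", "quintile", "measure", "value_from", "value_to",
           "diff", "pct")
}
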