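#' Initial state occupancy from the register
#'
#' Counts persons alive at the start of `year` by age, gender and quintile,
#' split into the disease-free and T2D states according to the ascertained
#' incidence year.
#'
#' @param register Long-format register tibble.
#' @param ascertainment Output of [ascertain_register()].
#' @param quintiles Tibble (person_id, quintile).
#' @param year Calendar year of the snapshot.
#' @return Tibble (age, gender, quintile, n_free, n_t2d) on the complete
#'   grid, zero-filled.
#' @export
initial_state <- function(register, ascertainment, quintiles, year = 2019) {
  snap <- register |>
    filter(.data$year == !!year) |>
    left_join(select(ascertainment, "person_id", "incidence_year"),
              by = "person_id") |>
    left_join(quintiles, by = "person_id") |>
    mutate(
      age = !!year - .data$birth_year,
      in_t2d = !is.na(.data$incidence_year) & .data$incidence_year <= !!year
    ) |>
    group_by(.data$age, .data$gender, .data$quintile) |>
    summarise(n_free = sum(!.data$in_t2d), n_t2d = sum(.data$in_t2d),
              .groups = "drop")
  expand_grid(age = AGE_MIN:AGE_MAX, gender = GENDERS, quintile = QUINTILES) |>
    left_join(snap, by = c("age", "gender", "quintile")) |>
    mutate(
      n_free = as.numeric(replace_na(.data$n_free, 0L)),
      n_t2d = as.numeric(replace_na(.data$n_t2d, 0L))
    )
}

#' Schedule of disease-free 30-year-old entrants
#'
#' Builds the per-year count of 30-year-olds entering the projection in the
#' disease-free state. With a register supplied, the future yearly total
#' defaults to the mean number of observed age-30 entrants over the last
#' five register years; otherwise `total_per_year` must be given. Entrants
#' are split 50/50 by gender and by `quintile_shares` across quintiles
#' (equal fifths by construction at entry).
#'
#' @param years Future calendar years covered by the schedule.
#' @param register Optional register to infer the yearly total from.
#' @param total_per_year Optional explicit yearly total of entrants.
#' @param quintile_shares Length-5 shares summing to 1.
#' @return Tibble (year, gender, quintile, n_entrants).
#' @export
entrant_schedule <- function(years, register = NULL, total_per_year = NULL,
                             quintile_shares = rep(0.2, 5)) {
  if (abs(sum(quintile_shares) - 1) > 1e-8) {
    abort("quintile shares must sum to 1")
  }
  if (is.null(total_per_year)) {
    if (is.null(register)) abort("supply either a register or total_per_year")
    ent <- register |>
      group_by(.data$person_id) |>
      summarise(first_year = min(.data$year), age_at_first = min(.data$year) -
                  .data$birth_year[1], .groups = "drop") |>
      filter(.data$age_at_first == AGE_MIN)
    last5 <- sort(unique(ent$first_year), decreasing = TRUE)[1:5]
    total_per_year <- nrow(ent[ent$first_year %in% last5, ]) / length(last5)
  }
  expand_grid(year = years, gender = GENDERS, quintile = QUINTILES) |>
    mutate(n_entrants = total_per_year / 2 *
             quintile_shares[quintile_index(.data$quintile)])
}

#' Advance the population one year through the illness-death model
#'
#' Deterministic cohort-component update with expected (real-valued) counts:
#' from the start-of-year disease-free count, `p_mF` die and `p_inc` become
#' incident; from the T2D count, `p_mT` die. Survivors age one year;
#' incident cases enter the T2D state at the year end (they are not exposed
#' to T2D mortality in their incidence year); entrants are added at age 30
#' in the disease-free state.
#'
#' @param state Tibble (age, gender, quintile, n_free, n_t2d).
#' @param probs_year One calendar year of a `transition_probs` set.
#' @param entrants_year Optional tibble (gender, quintile, n_entrants) added
#'   at age 30 next year.
#' @return List with `state` (next year's occupancy) and `flows` (per
#'   gender x quintile: incident cases and deaths by state).
#' @export
step_population <- function(state, probs_year, entrants_year = NULL) {
  df <- state |>
    left_join(
      select(probs_year, "age", "gender", "quintile", "p_inc", "p_mF", "p_mT"),
      by = c("age", "gender", "quintile")
    )
  occupied <- df$n_free > 0 | df$n_t2d > 0
  if (any(occupied & (is.na(df$p_mF) | is.na(df$p_mT) | is.na(df$p_inc)))) {
    abort("transition probabilities missing for occupied cells")
  }
  df <- df |>
    mutate(
      p_inc = replace_na(.data$p_inc, 0),
      p_mF = replace_na(.data$p_mF, 0),
      p_mT = replace_na(.data$p_mT, 0),
      deaths_free = .data$n_free * .data$p_mF,
      incident = .data$n_free * .data$p_inc,
      deaths_t2d = .data$n_t2d * .data$p_mT,
      next_free = .data$n_free - .data$deaths_free - .data$incident,
      next_t2d = .data$n_t2d - .data$deaths_t2d + .data$incident
    )
  if (any(df$next_free < -1e-9 | df$next_t2d < -1e-9)) {
    abort("negative occupancy produced; check p_inc + p_mF <= 1")
  }

  flows <- df |>
    group_by(.data$gender, .data$quintile) |>
    summarise(
      incident = sum(.data$incident),
      deaths_free = sum(.data$deaths_free),
      deaths_t2d = sum(.data$deaths_t2d),
      .groups = "drop"
    )

  # survivors age one year; the terminal age is absorbing (with the standard
  # closure p = 1 at age 100 it is never occupied at year start)
  aged <- df |>
    mutate(age = pmin(.data$age + 1L, AGE_MAX)) |>
    group_by(.data$age, .data$gender, .data$quintile) |>
    summarise(n_free = sum(.data$next_free), n_t2d = sum(.data$next_t2d),
              .groups = "drop")
  next_state <- expand_grid(
    age = AGE_MIN:AGE_MAX, gender = GENDERS, quintile = QUINTILES
  ) |>
    left_join(aged, by = c("age", "gender", "quintile")) |>
    mutate(n_free = replace_na(.data$n_free, 0),
           n_t2d = replace_na(.data$n_t2d, 0))
  if (!is.null(entrants_year)) {
    next_state <- next_state |>
      left_join(
        select(entrants_year, "gender", "quintile", "n_entrants"),
        by = c("gender", "quintile")
      ) |>
      mutate(n_free = .data$n_free +
               ifelse(.data$age == AGE_MIN, replace_na(.data$n_entrants, 0), 0)) |>
      select(-"n_entrants")
  }
  list(state = next_state, flows = flows)
}

#' Project state occupancy year by year
#'
#' Repeated application of [step_population()] from the initial year to the
#' horizon, recording occupancy and flows. Deterministic.
#'
#' @param initial Tibble (age, gender, quintile, n_free, n_t2d) at
#'   `start_year`.
#' @param probs A `transition_probs` set covering `start_year` to
#'   `horizon - 1`.
#' @param entrants Entrant schedule covering years `start_year + 1` to
#'   `horizon`, or `NULL` for no entrants.
#' @param start_year Calendar year of `initial`.
#' @param horizon Last projected calendar year.
#' @return A `population_trajectory` tibble (year, age, gender, quintile,
#'   n_free, n_t2d) with the per-year flow tallies in attribute `"flows"`.
#' @export
project_population <- function(initial, probs, entrants = NULL,
                               start_year = 2019, horizon = 2040) {
  if (start_year > horizon) abort("initial year must not exceed the horizon")
  states <- list(mutate(initial, year = start_year, .before = 1))
  flows <- list()
  state <- initial
  year <- start_year
  while (year < horizon) {
    ent <- if (!is.null(entrants)) filter(entrants, .data$year == !!year + 1L)
    res <- step_population(state, filter(probs, .data$year == !!year),
                           if (!is.null(ent) && nrow(ent)) ent)
    state <- res$state
    year <- year + 1L
    states[[length(states) + 1]] <- mutate(state, year = year, .before = 1)
    flows[[length(flows) + 1]] <- mutate(res$flows, year = year - 1L, .before = 1)
  }
  out <- bind_rows(states)
  attr(out, "flows") <- bind_rows(flows)
  class(out) <- c("population_trajectory", class(out))
  out
}

#' Stochastic microsimulation oracle for the deterministic projection
#'
#' Samples individual Bernoulli transitions with the same annual
#' probabilities as [project_population()], scaling `n_agents` agents to the
#' initial population. Its scaled occupancies converge to the deterministic
#' expected counts, providing an independent validation oracle.
#'
#' @param initial Initial occupancy tibble as in [project_population()].
#' @param probs,entrants,start_year,horizon As in [project_population()].
#' @param seed Integer seed for reproducibility.
#' @param n_agents Number of simulated agents.
#' @return A `population_trajectory` tibble of scaled occupancies; the
#'   population-to-agent scale factor is attached as attribute `"scale"`.
#' @export
microsim_oracle <- function(initial, probs, entrants = NULL,
                            start_year = 2019, horizon = 2040,
                            seed = 1L, n_agents = 1e5) {
  stopifnot(n_agents >= 1)
  set.seed(seed)
  total <- sum(initial$n_free) + sum(initial$n_t2d)
  scale <- total / n_agents
  arr <- probs_arrays(probs)

  cells <- initial |> filter(.data$n_free > 0 | .data$n_t2d > 0)
  w <- c(cells$n_free, cells$n_t2d)
  draw <- sample(length(w), n_agents, replace = TRUE, prob = w)
  k <- nrow(cells)
  cell <- ifelse(draw > k, draw - k, draw)
  agent_age <- cells$age[cell]
  agent_g <- match(cells$gender[cell], GENDERS)
  agent_q <- quintile_index(cells$quintile[cell])
  agent_t2d <- draw > k
  alive <- rep(TRUE, n_agents)

  occupancy <- function(year) {
    idx <- which(alive)
    if (!length(idx)) {
      return(expand_grid(age = AGE_MIN:AGE_MAX, gender = GENDERS,
                         quintile = QUINTILES) |>
               mutate(year = year, n_free = 0, n_t2d = 0) |>
               select("year", everything()))
    }
    tibble(
      age = agent_age[idx], gender = GENDERS[agent_g[idx]],
      quintile = QUINTILES[agent_q[idx]], t2d = agent_t2d[idx]
    ) |>
      group_by(.data$age, .data$gender, .data$quintile) |>
      summarise(n_free = sum(!.data$t2d) * scale,
                n_t2d = sum(.data$t2d) * scale, .groups = "drop") |>
      mutate(year = year, .before = 1)
  }

  states <- list(occupancy(start_year))
  for (t in start_year:(horizon - 1L)) {
    if (start_year >= horizon) break
    ti <- match(t, arr$years)
    if (is.na(ti)) abort(paste0("no probabilities for year ", t))
    idx <- which(alive)
    if (length(idx)) {
      ix <- cbind(agent_age[idx] - AGE_MIN + 1L, agent_g[idx], agent_q[idx], ti)
      u <- runif(length(idx))
      free <- !agent_t2d[idx]
      pf <- ifelse(free, arr$p_mF[ix], arr$p_mT[ix])
      pf[is.na(pf)] <- 0
      pi <- ifelse(free, arr$p_inc[ix], 0)
      pi[is.na(pi)] <- 0
      dies <- u < pf
      becomes <- !dies & free & u < pf + pi
      alive[idx[dies]] <- FALSE
      agent_t2d[idx[becomes]] <- TRUE
      agent_age[idx[!dies]] <- pmin(agent_age[idx[!dies]] + 1L, AGE_MAX)
    }
    if (!is.null(entrants)) {
      ent <- filter(entrants, .data$year == t + 1L)
      if (nrow(ent)) {
        counts <- round(ent$n_entrants / scale)
        n_new <- sum(counts)
        if (n_new > 0) {
          agent_age <- c(agent_age, rep(AGE_MIN, n_new))
          agent_g <- c(agent_g, rep(match(ent$gender, GENDERS), counts))
          agent_q <- c(agent_q, rep(quintile_index(ent$quintile), counts))
          agent_t2d <- c(agent_t2d, rep(FALSE, n_new))
          alive <- c(alive, rep(TRUE, n_new))
        }
      }
    }
    states[[length(states) + 1]] <- occupancy(t + 1L)
  }
  out <- bind_rows(states)
  attr(out, "scale") <- scale
  class(out) <- c("population_trajectory", class(out))
  out
}

#' Prevalent-case table by margin and year
#'
#' Tabulates projected T2D cases (and the T2D share of the population where
#' the disease-free counts are available) by a chosen margin, with absolute
#' and percentage changes between the first requested year and each later
#' one. For the quintile margin a `Q5-Q1` gap row is appended (gap
#' percentage relative to Q1).
#'
#' @param trajectory A `population_trajectory` tibble, or any tibble with
#'   columns `year`, `n_t2d`, optionally `n_free`, and the margin column
#'   (`quintile`, `gender`) or `age` (for `margin = "age_band"`).
#' @param years Calendar years to tabulate; changes are relative to the
#'   first.
#' @param margin One of `"quintile"`, `"gender"`, `"age_band"`.
#' @return Wide tibble with one row per group plus an `All` row, columns
#'   `cases_<year>`, `share_<year>` (proportion with T2D, if available),
#'   `diff_<first>_<later>` and `pct_<first>_<later>` (percentage change,
#'   `(late - early) / early * 100`).
#' @export
prevalence_table <- function(trajectory, years = c(2020, 2030, 2040),
                             margin = c("quintile", "gender", "age_band")) {
  margin <- match.arg(margin)
  missing_years <- setdiff(years, unique(trajectory$year))
  if (length(missing_years)) {
    abort(paste0("trajectory does not cover year(s) ",
                 paste(missing_years, collapse = ", ")))
  }
  df <- trajectory |> filter(.data$year %in% years)
  df$group <- switch(margin,
    quintile = df$quintile,
    gender = df$gender,
    age_band = age_band_table(df$age)
  )
  has_free <- "n_free" %in% names(df)
  tally <- function(d, label) {
    d |>
      group_by(.data$group, .data$year) |>
      summarise(
        cases = sum(.data$n_t2d),
        pop = if (has_free) sum(.data$n_free + .data$n_t2d) else NA_real_,
        .groups = "drop"
      )
  }
  long <- bind_rows(
    tally(df) ,
    df |> mutate(group = "All") |> tally()
  ) |>
    mutate(share = .data$cases / .data$pop)

  wide <- long |>
    select("group", "year", "cases", "share") |>
    pivot_wider(names_from = "year", values_from = c("cases", "share"),
                names_sep = "_")
  y0 <- years[1]
  for (y in setdiff(years, y0)) {
    early <- wide[[paste0("cases_", y0)]]
    late <- wide[[paste0("cases_", y)]]
    wide[[paste0("diff_", y0, "_", y)]] <- late - early
    wide[[paste0("pct_", y0, "_", y)]] <- (late - early) / early * 100
  }
  if (!has_free) wide <- select(wide, -starts_with("share_"))

  if (margin == "quintile" && all(c("Q1", "Q5") %in% wide$group)) {
    gap <- wide[wide$group == "Q5", ] |> mutate(group = "Q5-Q1")
    q1 <- wide[wide$group == "Q1", ]
    for (y in years) {
      cn <- paste0("cases_", y)
      gap[[cn]] <- gap[[cn]] - q1[[cn]]
      gap[[paste0("gap_pct_", y)]] <- gap[[cn]] / q1[[cn]] * 100
      if (has_free) gap[[paste0("share_", y)]] <- NA_real_
    }
    gap <- select(gap, -starts_with("diff_"), -starts_with("pct_"))
    wide <- bind_rows(wide, gap)
  }
  order_groups <- c("All", sort(setdiff(wide$group, c("All", "Q5-Q1"))), "Q5-Q1")
  wide[match(intersect(order_groups, wide$group), wide$group), ]
}
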