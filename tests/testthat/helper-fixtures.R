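# shared fixture builders; expensive objects are memoised for the test run

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, expr, envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# one person's long-format history for ascertainment tests
mk_person <- function(id = "P1", gender = "M", birth_year = 1950,
                      years, atc = "", grants = NULL, died_year = NA) {
  atc <- rep_len(atc, length(years))
  grant_type <- rep(NA_character_, length(years))
  if (!is.null(grants)) {
    for (y in names(grants)) grant_type[years == as.integer(y)] <- grants[[y]]
  }
  tibble::tibble(
    person_id = id, year = as.integer(years), gender = gender,
    birth_year = as.integer(birth_year),
    household_income = 30000, n_adults = 1L, n_children = 0L,
    atc_codes = atc, grant_type = grant_type,
    died = !is.na(died_year) & years == died_year
  )
}

# transition-probability set on the full grid from per-field functions of
# (age, gender, quintile index, year); terminal age closed automatically
toy_probs <- function(years,
                      f_inc = function(a, g, q, y) 0.005,
                      f_mF = function(a, g, q, y) 0.01,
                      f_mT = function(a, g, q, y) 0.02) {
  grid <- tidyr::expand_grid(
    age = 30:100, gender = c("M", "F"), quintile = paste0("Q", 1:5),
    year = years
  )
  q <- as.integer(sub("Q", "", grid$quintile))
  grid$p_inc <- pmin(pmax(f_inc(grid$age, grid$gender, q, grid$year), 0), 1)
  grid$p_mF <- pmin(pmax(f_mF(grid$age, grid$gender, q, grid$year), 0), 1)
  grid$p_mT <- pmin(pmax(f_mT(grid$age, grid$gender, q, grid$year), 0), 1)
  terminal <- grid$age == 100
  grid$p_inc[terminal] <- 0
  grid$p_mF[terminal] <- 1
  grid$p_mT[terminal] <- 1
  grid <- dplyr::arrange(grid, year, gender, quintile, age)
  class(grid) <- c("transition_probs", class(grid))
  grid
}

# uniform starting population over ages 30-99
toy_state <- function(n_free = 100, n_t2d = 10) {
  tidyr::expand_grid(age = 30:100, gender = c("M", "F"),
                     quintile = paste0("Q", 1:5)) |>
    dplyr::mutate(n_free = ifelse(age < 100, n_free, 0),
                  n_t2d = ifelse(age < 100, n_t2d, 0))
}

small_register <- function(n = 4000L, seed = 11L) {
  memo(paste0("reg_", n, "_", seed), {
    cfg <- default_config(seed = seed)
    cfg$n_persons <- as.integer(n)
    generate_register(cfg)
  })
}

truth_quintiles <- function(reg) {
  dplyr::select(reg$truth$persons, person_id, quintile = quintile_true)
}

small_counts <- function(n = 4000L, seed = 11L) {
  memo(paste0("counts_", n, "_", seed), {
    reg <- small_register(n, seed)
    aggregate_counts(reg$register, ascertain_register(reg$register),
                     truth_quintiles(reg))
  })
}

small_smoothed <- function(n = 4000L, seed = 11L) {
  memo(paste0("smoothed_", n, "_", seed), {
    suppressMessages(smooth_over_age(
      estimate_transition_probabilities(small_counts(n, seed))
    ))
  })
}

# full-scale fixture used by the acceptance suite (built once)
acceptance_fixture <- function() {
  memo("acceptance", {
    cfg <- default_config(seed = 1L)
    cfg$n_persons <- 100000L
    reg <- generate_register(cfg)
    asc <- ascertain_register(reg$register)
    quin <- truth_quintiles(reg)
    counts <- aggregate_counts(reg$register, asc, quin)
    probs <- suppressMessages(smooth_over_age(
      estimate_transition_probabilities(counts)
    ))
    scen <- suppressWarnings(suppressMessages(build_all_scenarios(
      probs, assumptions = cfg$obesity
    )))
    init <- initial_state(reg$register, asc, quin, 2019)
    entrants <- entrant_schedule(2020:2040, register = reg$register)
    trajectories <- lapply(scen[c("baseline", "A", "B", "C")], function(p) {
      project_population(init, p, entrants, 2019, 2040)
    })
    list(cfg = cfg, reg = reg, asc = asc, quin = quin, counts = counts,
         probs = probs, scen = scen, init = init, entrants = entrants,
         trajectories = trajectories)
  })
}
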