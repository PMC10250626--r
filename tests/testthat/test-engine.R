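one_cell_state <- function(age = 50, n_free = 0, n_t2d = 0) {
  tidyr::expand_grid(age = 30:100, gender = c("M", "F"),
                     quintile = paste0("Q", 1:5)) |>
    dplyr::mutate(
      n_free = ifelse(age == !!age & gender == "M" & quintile == "Q3",
                      n_free, 0),
      n_t2d = ifelse(age == !!age & gender == "M" & quintile == "Q3",
                     n_t2d, 0)
    )
}

test_that("one projection step reproduces the hand-computed update", {
  state <- one_cell_state(50, n_free = 1000, n_t2d = 200)
  probs <- toy_probs(years = 2020,
                     f_inc = function(a, g, q, y) 0.1,
                     f_mF = function(a, g, q, y) 0.05,
                     f_mT = function(a, g, q, y) 0.2)
  res <- step_population(state, probs)
  nxt <- res$state
  cell <- nxt$age == 51 & nxt$gender == "M" & nxt$quintile == "Q3"
  expect_equal(nxt$n_free[cell], 850)   # 1000 - 50 deaths - 100 incident
  expect_equal(nxt$n_t2d[cell], 260)    # 200 - 40 deaths + 100 incident
  fl <- res$flows[res$flows$gender == "M" & res$flows$quintile == "Q3", ]
  expect_equal(fl$incident, 100)
  expect_equal(fl$deaths_free + fl$deaths_t2d, 90)
})

test_that("zero probabilities shift ages; unit mortality empties the state", {
  state <- toy_state(100, 10)
  zero <- toy_probs(years = 2020,
                    f_inc = function(a, g, q, y) 0,
                    f_mF = function(a, g, q, y) 0,
                    f_mT = function(a, g, q, y) 0)
  zero$p_mF[zero$age == 100] <- 0  # disable the terminal closure too
  zero$p_mT[zero$age == 100] <- 0
  res <- step_population(state, zero)
  expect_equal(res$state$n_free[res$state$age == 45],
               state$n_free[state$age == 44])
  expect_equal(sum(res$state$n_free + res$state$n_t2d),
               sum(state$n_free + state$n_t2d))

  lethal <- toy_probs(years = 2020,
                      f_mF = function(a, g, q, y) 1,
                      f_mT = function(a, g, q, y) 1)
  lethal$p_inc <- 0
  ent <- tidyr::expand_grid(year = 2021, gender = c("M", "F"),
                            quintile = paste0("Q", 1:5)) |>
    dplyr::mutate(n_entrants = 7)
  res2 <- step_population(state, lethal, ent)
  expect_equal(sum(res2$state$n_free), 70)  # only the entrants remain
  expect_equal(sum(res2$state$n_t2d), 0)
  expect_true(all(res2$state$n_free[res2$state$age > 30] == 0))
})

test_that("a horizon equal to the start year gives a length-one trajectory", {
  state <- toy_state()
  probs <- toy_probs(years = 2019)
  tr <- project_population(state, probs, NULL, 2019, 2019)
  expect_equal(unique(tr$year), 2019)
  expect_equal(sum(tr$n_free), sum(state$n_free))
})

test_that("persons are conserved at every projection step", {
  reg <- small_register()
  proj <- hold_incidence_constant(
    suppressMessages(fit_mortality_trend(small_smoothed())), 2019
  )
  asc <- ascertain_register(reg$register)
  init <- initial_state(reg$register, asc, truth_quintiles(reg), 2019)
  ent <- entrant_schedule(2020:2040, register = reg$register)
  tr <- project_population(init, proj, ent, 2019, 2040)
  flows <- attr(tr, "flows")
  totals <- tr |> dplyr::group_by(year) |>
    dplyr::summarise(n = sum(n_free + n_t2d))
  for (y in 2020:2040) {
    deaths <- sum(flows$deaths_free[flows$year == y - 1] +
                    flows$deaths_t2d[flows$year == y - 1])
    entr <- sum(ent$n_entrants[ent$year == y])
    expect_equal(totals$n[totals$year == y],
                 totals$n[totals$year == y - 1] - deaths + entr,
                 tolerance = 1e-9)
  }
})

test_that("raising incidence raises future T2D and lowers future free counts", {
  state <- toy_state(100, 10)
  base <- toy_probs(years = 2019:2025)
  bumped <- base
  up <- bumped$age == 60 & bumped$gender == "F" & bumped$quintile == "Q2"
  bumped$p_inc[up] <- bumped$p_inc[up] + 0.05
  tr_a <- project_population(state, base, NULL, 2019, 2025)
  tr_b <- project_population(state, bumped, NULL, 2019, 2025)
  expect_true(all(tr_b$n_t2d - tr_a$n_t2d >= -1e-12))
  expect_true(all(tr_b$n_free - tr_a$n_free <= 1e-12))
  expect_gt(sum(tr_b$n_t2d[tr_b$year == 2025]),
            sum(tr_a$n_t2d[tr_a$year == 2025]))
})

test_that("the microsimulation agrees exactly under degenerate probabilities", {
  state <- one_cell_state(40, n_free = 500)
  det <- toy_probs(years = 2019:2023,
                   f_inc = function(a, g, q, y) ifelse(a == 41, 1, 0),
                   f_mF = function(a, g, q, y) 0,
                   f_mT = function(a, g, q, y) ifelse(a == 43, 1, 0))
  tr <- project_population(state, det, NULL, 2019, 2023)
  ms <- microsim_oracle(state, det, NULL, 2019, 2023, seed = 4, n_agents = 500)
  j <- dplyr::inner_join(tr, ms, by = c("year", "age", "gender", "quintile"),
                         suffix = c("_det", "_ms"))
  expect_equal(j$n_free_ms, j$n_free_det, tolerance = 1e-12)
  expect_equal(j$n_t2d_ms, j$n_t2d_det, tolerance = 1e-12)
})

test_that("the microsimulation is reproducible under a fixed seed", {
  state <- toy_state(50, 5)
  probs <- toy_probs(years = 2019:2024)
  a <- microsim_oracle(state, probs, NULL, 2019, 2024, seed = 9,
                       n_agents = 2000)
  b <- microsim_oracle(state, probs, NULL, 2019, 2024, seed = 9,
                       n_agents = 2000)
  expect_identical(a, b)
})

test_that("prevalence tables are marginally consistent", {
  reg <- small_register()
  asc <- ascertain_register(reg$register)
  init <- initial_state(reg$register, asc, truth_quintiles(reg), 2019)
  probs <- hold_incidence_constant(
    suppressMessages(fit_mortality_trend(small_smoothed())), 2019
  )
  ent <- entrant_schedule(2020:2040, register = reg$register)
  tr <- project_population(init, probs, ent, 2019, 2040)
  pt <- prevalence_table(tr, years = c(2020, 2030, 2040))
  all_row <- pt[pt$group == "All", ]
  q_rows <- pt[pt$group %in% paste0("Q", 1:5), ]
  for (y in c(2020, 2030, 2040)) {
    expect_equal(sum(q_rows[[paste0("cases_", y)]]),
                 all_row[[paste0("cases_", y)]], tolerance = 1e-9)
  }
  # percentage change is (late - early) / early
  expect_equal(all_row$pct_2020_2040,
               (all_row$cases_2040 - all_row$cases_2020) /
                 all_row$cases_2020 * 100, tolerance = 1e-12)
  # gap row
  gap <- pt[pt$group == "Q5-Q1", ]
  expect_equal(gap$cases_2020,
               q_rows$cases_2020[q_rows$group == "Q5"] -
                 q_rows$cases_2020[q_rows$group == "Q1"], tolerance = 1e-9)
  # gender margin sums to the same total
  pg <- prevalence_table(tr, years = 2020, margin = "gender")
  expect_equal(pg$cases_2020[pg$group == "All"], all_row$cases_2020,
               tolerance = 1e-9)
  expect_error(prevalence_table(tr, years = 2050), "cover")
})

test_that("prevalence grows when incidence is constant and mortality falls", {
  state <- toy_state(1000, 30)
  probs <- toy_probs(
    years = 2019:2035,
    f_inc = function(a, g, q, y) 0.004 + 0.008 * exp(-((a - 68) / 14)^2),
    f_mF = function(a, g, q, y) 0.002 * exp(0.07 * (a - 30)) * 0.985^(y - 2019),
    f_mT = function(a, g, q, y) 0.004 * exp(0.07 * (a - 30)) * 0.985^(y - 2019)
  )
  ent <- tidyr::expand_grid(year = 2020:2035, gender = c("M", "F"),
                            quintile = paste0("Q", 1:5)) |>
    dplyr::mutate(n_entrants = 100)
  tr <- project_population(state, probs, ent, 2019, 2035)
  yearly <- tr |> dplyr::group_by(year) |> dplyr::summarise(t2d = sum(n_t2d))
  expect_true(all(diff(yearly$t2d) > 0))
})
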