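#' Generate a register-like synthetic population with known ground truth
#'
#' Simulates individual illness-death trajectories from the ground-truth
#' transition schedule ([truth_schedule()]) and writes medication-purchase
#' and reimbursement-grant histories such that [ascertain_register()]
#' recovers the simulated disease state exactly: every observed case
#' qualifies through one of the five criteria (grants, secretagogue
#' purchases, or A10B/insulin year counting) and its recovered incidence
#' year equals the simulated register-entry year. A configurable fraction of
#' never-diseased persons purchase insulin only (a type 1 diabetes-like
#' pattern) and are correctly left unclassified.
#'
#' The initial population is seeded at the start of the observation window
#' with a steady-state T2D prevalence by age implied by the first year's
#' schedule; a new cohort of disease-free 30-year-olds enters every
#' subsequent year. Household income is drawn per person so that equivalized
#' income ranks recover the planted quintile.
#'
#' @param config Configuration list, see [default_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return A list of class `t2d_register` with elements `register` (long
#'   person-year tibble: person_id, year, gender, birth_year,
#'   household_income, n_adults, n_children, atc_codes, grant_type, died)
#'   and `truth` (list: `schedule`, the full ground-truth
#'   [truth_schedule()] through the projection horizon, and `persons`, one
#'   row per simulated person with the true quintile, incidence year and
#'   death year).
#' @export
generate_register <- function(config = default_config(), seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)

  y0 <- config$years[1]
  y1 <- config$years[2]
  sched_obs <- truth_schedule(config, years = y0:y1)
  arr <- probs_arrays(sched_obs)

  # --- initial population ---------------------------------------------------
  n0 <- config$n_persons
  age_weights <- exp(-0.035 * (0:(AGE_MAX - AGE_MIN)))
  age0 <- sample(AGE_MIN:AGE_MAX, n0, replace = TRUE, prob = age_weights)
  gender <- sample(GENDERS, n0, replace = TRUE)
  quintile <- sample(QUINTILES, n0, replace = TRUE,
                     prob = config$entrant_quintile_shares)
  prev0 <- steady_state_prevalence(sched_obs[sched_obs$year == y0, ])
  p_prev <- prev0[cbind(age0 - AGE_MIN + 1L, match(gender, GENDERS),
                        quintile_index(quintile))]
  prevalent <- runif(n0) < p_prev

  byear <- y0 - age0
  entry_year <- rep(y0, n0)
  t_inc <- ifelse(prevalent, y0, NA_integer_)
  death_year <- rep(NA_integer_, n0)

  n_entrants <- round(config$n_persons * config$entrant_rate)

  # --- annual transitions ---------------------------------------------------
  for (t in y0:y1) {
    if (t > y0 && n_entrants > 0) {
      byear <- c(byear, rep(t - AGE_MIN, n_entrants))
      gender <- c(gender, sample(GENDERS, n_entrants, replace = TRUE))
      quintile <- c(quintile, sample(QUINTILES, n_entrants, replace = TRUE,
                                     prob = config$entrant_quintile_shares))
      entry_year <- c(entry_year, rep(t, n_entrants))
      t_inc <- c(t_inc, rep(NA_integer_, n_entrants))
      death_year <- c(death_year, rep(NA_integer_, n_entrants))
      prevalent <- c(prevalent, rep(FALSE, n_entrants))
    }
    age <- t - byear
    alive <- is.na(death_year) & entry_year <= t
    in_t2d <- alive & !is.na(t_inc) & t_inc <= t
    in_free <- alive & !in_t2d
    ti <- match(t, arr$years)

    if (any(in_free)) {
      i <- which(in_free)
      ix <- cbind(age[i] - AGE_MIN + 1L, match(gender[i], GENDERS),
                  quintile_index(quintile[i]), ti)
      pf <- arr$p_mF[ix]
      pi <- arr$p_inc[ix]
      u <- runif(length(i))
      death_year[i[u < pf]] <- t
      t_inc[i[u >= pf & u < pf + pi]] <- t + 1L
    }
    if (any(in_t2d)) {
      i <- which(in_t2d)
      ix <- cbind(age[i] - AGE_MIN + 1L, match(gender[i], GENDERS),
                  quintile_index(quintile[i]), ti)
      u <- runif(length(i))
      death_year[i[u < arr$p_mT[ix]]] <- t
    }
  }

  n <- length(byear)
  person_id <- sprintf("P%07d", seq_len(n))
  last_year <- pmin(ifelse(is.na(death_year), y1, death_year), y1)
  t_inc_obs <- ifelse(!is.na(t_inc) & t_inc <= last_year, t_inc, NA_integer_)
  observed_case <- !is.na(t_inc_obs)

  # --- medication subtype and grants for observed cases ---------------------
  asc <- config$ascertainment
  u_sub <- runif(n)
  subtype <- rep("metformin", n)
  subtype[u_sub < asc$secretagogue_fraction] <- "secretagogue"
  lo <- asc$secretagogue_fraction
  subtype[u_sub >= lo & u_sub < lo + asc$insulin_later_fraction] <- "ins_later"
  lo <- lo + asc$insulin_later_fraction
  subtype[u_sub >= lo & u_sub < lo + asc$insulin_equal_fraction] <- "ins_equal"
  # equal purchase-year counts only qualify at onset age 40+; younger onsets
  # start insulin later instead so the case remains ascertainable
  onset_age <- t_inc_obs - byear
  subtype[subtype == "ins_equal" & !is.na(onset_age) & onset_age < 40] <- "ins_later"
  subtype[!observed_case] <- NA_character_

  has_grant <- observed_case & runif(n) < asc$grant_fraction
  grant_kind <- ifelse(
    has_grant,
    ifelse(runif(n) < asc$unspecified_grant_fraction, "unspecified", "T2D_specific"),
    NA_character_
  )

  noise <- !observed_case & runif(n) < asc$insulin_only_fraction
  noise_start <- ifelse(
    noise,
    entry_year + floor(runif(n) * (last_year - entry_year + 1)),
    NA_integer_
  )

  # --- household income -----------------------------------------------------
  q <- quintile_index(quintile)
  eq_base <- (5 - q) * 20000 + 12000 + runif(n) * 16000  # Q1 highest income
  n_adults <- sample(1:2, n, replace = TRUE, prob = c(0.35, 0.65))
  entry_age <- entry_year - byear
  n_children <- ifelse(
    entry_age < 55,
    sample(0:2, n, replace = TRUE, prob = c(0.60, 0.25, 0.15)),
    0L
  )
  eq_weight <- 1 + 0.5 * (n_adults - 1) + 0.3 * n_children

  # --- expand to person-years ----------------------------------------------
  n_years <- last_year - entry_year + 1L
  i <- rep.int(seq_len(n), n_years)
  year <- sequence(n_years, from = entry_year)

  on_meds <- observed_case[i] & year >= t_inc_obs[i]
  base_code <- ifelse(subtype[i] == "secretagogue", "A10BB01", "A10BA02")
  with_insulin <- on_meds & (
    (subtype[i] == "ins_later" & year >= t_inc_obs[i] + 2L) |
      subtype[i] == "ins_equal"
  )
  atc <- rep("", length(i))
  atc[on_meds] <- base_code[on_meds]
  atc[with_insulin] <- paste0(base_code[with_insulin], ";A10AB01")
  noise_on <- noise[i] & year >= noise_start[i]
  atc[noise_on] <- "A10AB01"

  grant_type <- rep(NA_character_, length(i))
  at_grant <- has_grant[i] & year == t_inc_obs[i]
  grant_type[at_grant] <- grant_kind[i][at_grant]

  register <- tibble(
    person_id = person_id[i],
    year = as.integer(year),
    gender = gender[i],
    birth_year = as.integer(byear[i]),
    household_income = eq_base[i] * eq_weight[i] * 1.015^(year - y0),
    n_adults = as.integer(n_adults[i]),
    n_children = as.integer(n_children[i]),
    atc_codes = atc,
    grant_type = grant_type,
    died = !is.na(death_year[i]) & year == death_year[i]
  )

  persons <- tibble(
    person_id = person_id,
    gender = gender,
    birth_year = as.integer(byear),
    quintile_true = quintile,
    entry_year = as.integer(entry_year),
    prevalent_at_entry = prevalent,
    t_inc = as.integer(t_inc),
    death_year = as.integer(death_year)
  )

  structure(
    list(
      register = register,
      truth = list(schedule = truth_schedule(config), persons = persons),
      config = config
    ),
    class = "t2d_register"
  )
}

#' @export
print.t2d_register <- function(x, ...) {
  p <- x$truth$persons
  cat("<t2d_register>\n")
  cat("  persons:     ", nrow(p), "\n")
  cat("  person-years:", nrow(x$register), "\n")
  cat("  years:       ", min(x$register$year), "-", max(x$register$year), "\n")
  cat("  observed T2D cases:",
      sum(!is.na(p$t_inc) & p$t_inc <= max(x$register$year)), "\n")
  invisible(x)
}

#' Write a synthetic register to CSV
#'
#' @param register Long-format register tibble (the `register` element of
#'   [generate_register()] output).
#' @param path Output file path.
#' @export
write_register_csv <- function(register, path) {
  write.csv(register, path, row.names = FALSE, na = "")
}
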