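#' Aggregate person-years into stratified occurrence/exposure counts
#'
#' Tallies person-years and events by age x gender x quintile x calendar
#' year. A person contributes to the disease-free state in every year before
#' the incidence year and to the T2D state from the incidence year onwards
#' (the transition occurs at the year boundary); deaths are attributed to
#' the state occupied in the year of death. The incidence event is counted
#' in the exposure year preceding the register entry: `n_incident` in year y
#' counts persons disease-free in y whose incidence year is y + 1, so that
#' `n_incident / n_free` estimates the exposure-year transition probability.
#'
#' @param register Long-format register tibble.
#' @param ascertainment Output of [ascertain_register()].
#' @param quintiles Tibble (person_id, quintile); e.g. the planted quintile
#'   from the generator truth, or [assign_income_quintiles()] output.
#' @return Tibble of class `strata_counts` on the complete
#'   age x gender x quintile x year grid with columns `n_free`,
#'   `n_incident`, `n_death_free`, `n_t2d`, `n_death_t2d`.
#' @export
aggregate_counts <- function(register, ascertainment, quintiles) {
  years <- if (nrow(register)) sort(unique(register$year)) else integer()
  grid <- expand_grid(
    age = AGE_MIN:AGE_MAX, gender = GENDERS, quintile = QUINTILES, year = years
  )
  if (nrow(register) == 0) {
    return(fill_zero_counts(grid))
  }

  df <- register |>
    select("person_id", "year", "gender", "birth_year", "died") |>
    left_join(select(ascertainment, "person_id", "incidence_year"),
              by = "person_id") |>
    left_join(quintiles, by = "person_id")
  if (anyNA(df$quintile)) abort("every person in the register needs a quintile")

  df <- df |>
    mutate(
      age = .data$year - .data$birth_year,
      in_t2d = !is.na(.data$incidence_year) & .data$year >= .data$incidence_year,
      incident = !.data$in_t2d & !is.na(.data$incidence_year) &
        .data$incidence_year == .data$year + 1L
    )
  if (any(df$incident & df$died)) {
    abort(paste0("inconsistent person-year: death in the disease-free state",
                 " and a transition to T2D recorded in the same year"))
  }

  counts <- df |>
    group_by(.data$age, .data$gender, .data$quintile, .data$year) |>
    summarise(
      n_free = sum(!.data$in_t2d),
      n_incident = sum(.data$incident),
      n_death_free = sum(!.data$in_t2d & .data$died),
      n_t2d = sum(.data$in_t2d),
      n_death_t2d = sum(.data$in_t2d & .data$died),
      .groups = "drop"
    )

  out <- grid |>
    left_join(counts, by = c("age", "gender", "quintile", "year")) |>
    mutate(across(starts_with("n_"), \(x) as.integer(replace_na(x, 0L))))
  validate_strata_counts(out)
  class(out) <- c("strata_counts", class(out))
  out
}

fill_zero_counts <- function(grid) {
  out <- grid |>
    mutate(n_free = 0L, n_incident = 0L, n_death_free = 0L,
           n_t2d = 0L, n_death_t2d = 0L)
  class(out) <- c("strata_counts", class(out))
  out
}

validate_strata_counts <- function(counts) {
  nmat <- as.matrix(counts[c("n_free", "n_incident", "n_death_free",
                             "n_t2d", "n_death_t2d")])
  if (any(nmat < 0)) abort("counts must be non-negative")
  if (any(counts$n_incident + counts$n_death_free > counts$n_free)) {
    abort("events exceed at-risk count in the disease-free state")
  }
  if (any(counts$n_death_t2d > counts$n_t2d)) {
    abort("T2D deaths exceed the T2D at-risk count")
  }
  invisible(counts)
}

#' Read/write stratified counts as CSV
#'
#' @param counts A `strata_counts` tibble.
#' @param path File path.
#' @return `read_strata_counts()` returns the counts tibble.
#' @export
write_strata_counts <- function(counts, path) {
  write.csv(counts, path, row.names = FALSE)
}

#' @rdname write_strata_counts
#' @export
read_strata_counts <- function(path) {
  out <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_strata_counts(out)
  class(out) <- c("strata_counts", class(out))
  out
}
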