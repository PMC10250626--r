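#' Equivalize household income with the OECD-modified scale
#'
#' Divides disposable household income by the OECD-modified equivalence
#' weight: 1.0 for the first adult, 0.5 for each further adult and 0.3 for
#' each child.
#'
#' @param household_income Numeric vector of household disposable income
#'   (currency/year), non-negative.
#' @param n_adults Integer vector, number of adults (>= 1).
#' @param n_children Integer vector, number of children (>= 0).
#' @return Equivalized income per consumption unit.
#' @examples
#' equivalize_income(42000, 2, 2)  # 42000 / 2.1 = 20000
#' @export
equivalize_income <- function(household_income, n_adults, n_children) {
  if (any(n_adults < 1, na.rm = TRUE)) {
    abort("invalid household composition: every household needs >= 1 adult")
  }
  if (any(n_children < 0, na.rm = TRUE)) {
    abort("invalid household composition: n_children must be >= 0")
  }
  if (any(household_income < 0, na.rm = TRUE)) {
    abort("household income must be non-negative")
  }
  household_income / (1.0 + 0.5 * (n_adults - 1) + 0.3 * n_children)
}

#' Assign income quintiles within 5-year age strata
#'
#' Ranks all persons alive in `year` by equivalized household income within
#' their 5-year age stratum and splits each stratum into five equal-sized
#' groups (sizes differing by at most one). Q1 is the *highest* income group
#' and Q5 the most deprived. Ties are broken by stable `person_id` order so
#' the assignment is deterministic.
#'
#' @param records Long-format register tibble with at least `person_id`,
#'   `year`, `birth_year`, `household_income`, `n_adults`, `n_children`.
#' @param year Calendar year in which to rank.
#' @return Tibble (person_id, quintile) for persons present in `year`.
#' @export
assign_income_quintiles <- function(records, year) {
  yr <- records[records$year == year, , drop = FALSE]
  if (nrow(yr) == 0) {
    warn(paste0("no persons present in year ", year, "; no quintiles assigned"))
    return(tibble(person_id = character(), quintile = character()))
  }
  yr$eq_income <- equivalize_income(yr$household_income, yr$n_adults, yr$n_children)
  yr$stratum <- age_stratum_5y(year - yr$birth_year)
  yr |>
    group_by(.data$stratum) |>
    arrange(desc(.data$eq_income), .data$person_id, .by_group = TRUE) |>
    mutate(quintile = QUINTILES[(5L * (row_number() - 1L)) %/% n() + 1L]) |>
    ungroup() |>
    select("person_id", "quintile") |>
    arrange(.data$person_id)
}
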