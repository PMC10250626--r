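# ATC classes used by the ascertainment rules:
#  - A10B  : blood-glucose lowering drugs excluding insulins
#  - A10A  : insulins and analogues
#  - insulin-secretion stimulating subclasses: A10BB (sulfonylureas),
#    A10BH (DPP-4 inhibitors), A10BX02/03/04 (glinides and other secretagogues)
RE_A10B <- "(^|;)A10B"
RE_A10A <- "(^|;)A10A"
RE_SECRETAGOGUE <- "(^|;)(A10BB|A10BH|A10BX02|A10BX03|A10BX04)"

#' Ascertain pharmacologically treated T2D from purchase and grant history
#'
#' A person is classified as having T2D if at least one of five criteria
#' holds: (1) a special-reimbursement grant with a T2D-specific diagnosis;
#' (2) any purchase of insulin-secretion stimulating medication (ATC A10BB,
#' A10BH, A10BX02, A10BX03, A10BX04); (3) more calendar years with any A10B
#' purchase than years with insulin (A10A) purchases; (4) equally many such
#' years and age 40+ at the first diabetes-medication purchase; or (5) a
#' grant with an unspecified diabetes diagnosis received at age 40+.
#' The incidence year is the earliest entry in the reimbursement register
#' (first purchase or grant year).
#'
#' @param person Long-format history of a single person: one row per year
#'   with columns `person_id`, `year`, `birth_year`, `atc_codes`
#'   (semicolon-joined ATC codes, `""` or `NA` if none) and `grant_type`
#'   (`"T2D_specific"`, `"unspecified"` or `NA`).
#' @return One-row tibble (person_id, is_t2d, incidence_year,
#'   triggering_criterion); the last two are `NA` when `is_t2d` is `FALSE`.
#' @export
ascertain_t2d <- function(person) {
  if (nrow(person) > 0 && length(unique(person$person_id)) > 1) {
    abort("ascertain_t2d() expects the history of a single person")
  }
  res <- ascertain_register(person)
  if (nrow(res) == 0) {
    return(tibble(
      person_id = NA_character_, is_t2d = FALSE,
      incidence_year = NA_integer_, triggering_criterion = NA_integer_
    ))
  }
  res
}

#' Vectorized T2D ascertainment over a whole register
#'
#' Applies the five-criteria classification of [ascertain_t2d()] to every
#' person in a long-format register.
#'
#' @param register Long-format register tibble (one row per person-year).
#' @return Tibble with one row per person: `person_id`, `is_t2d`,
#'   `incidence_year`, `triggering_criterion`.
#' @export
ascertain_register <- function(register) {
  if (nrow(register) == 0) {
    return(tibble(
      person_id = character(), is_t2d = logical(),
      incidence_year = integer(), triggering_criterion = integer()
    ))
  }
  atc <- register$atc_codes
  atc[is.na(atc)] <- ""
  has_a10b <- grepl(RE_A10B, atc)
  has_a10a <- grepl(RE_A10A, atc)
  has_secr <- grepl(RE_SECRETAGOGUE, atc)
  grant <- register$grant_type

  per <- tibble(
    person_id = register$person_id,
    year = register$year,
    birth_year = register$birth_year,
    has_a10b = has_a10b, has_a10a = has_a10a, has_secr = has_secr,
    grant_t2d = !is.na(grant) & grant == "T2D_specific",
    grant_unspec = !is.na(grant) & grant == "unspecified"
  ) |>
    group_by(.data$person_id) |>
    summarise(
      birth_year = .data$birth_year[1],
      yrs_a10b = sum(.data$has_a10b),
      yrs_insulin = sum(.data$has_a10a),
      any_secr = any(.data$has_secr),
      any_grant_t2d = any(.data$grant_t2d),
      grant_unspec_40 = any(.data$grant_unspec &
        (.data$year - .data$birth_year >= 40)),
      first_purchase = if (any(.data$has_a10b | .data$has_a10a)) {
        min(.data$year[.data$has_a10b | .data$has_a10a])
      } else NA_integer_,
      first_entry = {
        entry <- .data$year[.data$has_a10b | .data$has_a10a |
          .data$grant_t2d | .data$grant_unspec]
        if (length(entry)) min(entry) else NA_integer_
      },
      .groups = "drop"
    )

  age_first <- per$first_purchase - per$birth_year
  c1 <- per$any_grant_t2d
  c2 <- per$any_secr
  c3 <- per$yrs_a10b > per$yrs_insulin
  c4 <- per$yrs_a10b == per$yrs_insulin & per$yrs_a10b > 0 &
    !is.na(age_first) & age_first >= 40
  c5 <- per$grant_unspec_40
  crit <- cbind(c1, c2, c3, c4, c5)
  is_t2d <- rowSums(crit) > 0
  triggering <- ifelse(is_t2d, max.col(crit, ties.method = "first"), NA_integer_)

  tibble(
    person_id = per$person_id,
    is_t2d = is_t2d,
    incidence_year = ifelse(is_t2d, per$first_entry, NA_integer_),
    triggering_criterion = as.integer(triggering)
  )
}
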