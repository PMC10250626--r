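#' Population attributable fraction of obesity (Levin's formula)
#'
#' For a dichotomous exposure with prevalence `p` and relative risk `RR`,
#' the attributable fraction is `PAF = p (RR - 1) / (1 + p (RR - 1))`,
#' computed separately for T2D incidence and for mortality from T2D. The
#' exposure-outcome association is assumed identical across income groups.
#'
#' @param assumptions List with `prevalence` (single proportion or a vector
#'   named by gender), `rr_incidence` and `rr_mortality` (unitless relative
#'   risks, obese vs non-obese).
#' @return Tibble (gender, paf_incidence, paf_mortality).
#' @examples
#' compute_paf(list(prevalence = 0.2, rr_incidence = 2, rr_mortality = 2))
#' @export
compute_paf <- function(assumptions) {
  p <- unlist(assumptions$prevalence)  # YAML mappings arrive as lists
  if (is.null(names(p))) p <- setNames(rep(p[1], 2), GENDERS)
  p <- p[GENDERS]
  rrs <- c(assumptions$rr_incidence, assumptions$rr_mortality)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("obesity prevalence must lie in [0, 1]")
  }
  if (any(!is.finite(rrs)) || any(rrs < 0)) {
    abort("relative risks must be non-negative")
  }
  levin <- function(p, rr) p * (rr - 1) / (1 + p * (rr - 1))
  tibble(
    gender = GENDERS,
    paf_incidence = unname(levin(p, assumptions$rr_incidence)),
    paf_mortality = unname(levin(p, assumptions$rr_mortality))
  )
}

#' Apply an obesity counterfactual to a projected transition set
#'
#' Scenario B multiplies future T2D incidence and T2D mortality by
#' `1 - PAF` (elimination of the obesity-related excess risk); scenario C
#' multiplies them by `1 + PAF` (a doubled obesity contribution). Mortality
#' in the disease-free state and all historical years are untouched;
#' results are clamped to \[0, 1\].
#'
#' @param probsA The scenario-A projected `transition_probs` set.
#' @param scenario `"B"` or `"C"` (or a list with a `name` element).
#' @param paf PAF schedule from [compute_paf()].
#' @param from_year First calendar year the multiplier applies to
#'   (multipliers act on years strictly after the 2019 reference).
#' @return A `transition_probs` tibble.
#' @export
apply_scenario <- function(probsA, scenario, paf, from_year = 2020) {
  name <- if (is.list(scenario)) scenario$name else scenario
  if (!name %in% c("baseline", "A", "B", "C")) {
    abort("scenario must be one of baseline, A, B, C")
  }
  if (name %in% c("baseline", "A")) return(probsA)
  sign <- if (name == "B") -1 else 1
  out <- probsA |>
    left_join(paf, by = "gender") |>
    mutate(
      m_inc = ifelse(.data$year >= from_year, 1 + sign * .data$paf_incidence, 1),
      m_mort = ifelse(.data$year >= from_year, 1 + sign * .data$paf_mortality, 1)
    )
  new_inc <- out$p_inc * out$m_inc
  new_mT <- out$p_mT * out$m_mort
  clamped <- sum(new_inc > 1 | new_mT > 1, na.rm = TRUE)
  if (clamped > 0) inform(paste0("clamped ", clamped, " multiplied cells to 1"))
  out$p_inc <- clamp(new_inc, 0, 1)
  out$p_mT <- clamp(new_mT, 0, 1)
  out <- select(out, -"paf_incidence", -"paf_mortality", -"m_inc", -"m_mort")
  enforce_row_constraints(out)
}

#' Build all four scenario transition sets
#'
#' From historical (smoothed) probabilities: `baseline` = incidence held
#' constant at the 2019 level with projected mortality; `A` = projected
#' declining incidence with the same projected mortality; `B`/`C` =
#' scenario A with future T2D incidence and T2D mortality multiplied by
#' `1 - PAF` / `1 + PAF`. All four share the same disease-free mortality.
#'
#' @param probs Historical `transition_probs` (smoothed, with counts).
#' @param assumptions Obesity assumptions, see [compute_paf()].
#' @param fit_years,target_years Passed to [fit_mortality_trend()].
#' @param trend_from,exclude_years Passed to [fit_incidence_trend()].
#' @param mortality_pool,incidence_pool Trend-slope pooling levels.
#' @return Named list of `transition_probs` tibbles with attribute `"paf"`.
#' @export
build_all_scenarios <- function(probs, assumptions = default_config()$obesity,
                                fit_years = 1995:2018,
                                target_years = 2019:2040,
                                trend_from = 2011, exclude_years = 2007:2010,
                                mortality_pool = "gender",
                                incidence_pool = "gender") {
  mort <- fit_mortality_trend(probs, fit_years = fit_years,
                              target_years = target_years,
                              pool = mortality_pool)
  baseline <- hold_incidence_constant(mort, at_year = min(target_years))
  scenA <- fit_incidence_trend(mort, trend_from = trend_from,
                               exclude_years = exclude_years,
                               target_years = target_years,
                               pool = incidence_pool)
  paf <- compute_paf(assumptions)
  out <- list(
    baseline = baseline,
    A = scenA,
    B = apply_scenario(scenA, "B", paf),
    C = apply_scenario(scenA, "C", paf)
  )
  attr(out, "paf") <- paf
  out
}
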