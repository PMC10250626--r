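#' Default configuration for the synthetic register and projection pipeline
#'
#' Returns the full set of tunable parameters as a nested list. The defaults
#' describe the study conditions the synthetic register emulates: a population
#' aged 30-100 followed 1995-2019 in two genders and five income quintiles,
#' with T2D incidence peaking after age 60 (earlier and higher in lower
#' quintiles, higher in men), a diagnosis-campaign bump in 2007-2010, a
#' post-2011 declining incidence trend, Gompertz background mortality with an
#' income gradient and a T2D excess that diminishes with age, and a secular
#' mortality decline.
#'
#' @param seed Integer seed controlling all randomness downstream.
#' @return Nested list of parameters; see the methods vignette for the
#'   meaning, units and rationale of each entry.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    n_persons = 50000L,        # initial population aged 30+ in the first year
    entrant_rate = 0.016,      # yearly 30-year-old entrants, fraction of n_persons
    years = c(1995L, 2019L),   # observation window of the register
    horizon = 2040L,           # last projected calendar year
    incidence = list(
      base = 5e-4,             # annual probability floor at young ages
      peak = 0.012,            # added annual probability at the peak age
      peak_age = 70,           # peak age in the highest income quintile
      peak_width = 14,         # Gaussian width (years) of the age profile
      male_mult = 1.20,
      female_mult = 0.85,
      quintile_mult = c(0.80, 0.90, 1.00, 1.12, 1.26),  # Q1 .. Q5
      quintile_peak_shift = -1.0,  # years earlier per quintile step towards Q5
      decline_from = 2011L,    # first exposure year of the secular decline
      decline_rate = 0.015,    # multiplicative decline per year from decline_from
      bump_years = 2007:2010,  # diagnosis-campaign bump (exposure years)
      bump_height = 1.3        # multiplicative bump factor
    ),
    mortality = list(
      gompertz_a = 6e-4,       # hazard at age 30
      gompertz_b = 0.085,      # log-hazard slope per year of age
      male_mult = 1.50,
      female_mult = 0.75,
      quintile_mult = c(0.80, 0.90, 1.00, 1.10, 1.20),  # Q1 .. Q5
      t2d_hr_base = 2.5,       # T2D excess hazard ratio minus 1 at age 30
      t2d_hr_decay = 25,       # e-folding age span of the excess
      decline_rate = 0.015     # secular hazard decline per calendar year
    ),
    ascertainment = list(
      grant_fraction = 0.30,          # true cases also receiving a grant
      unspecified_grant_fraction = 0.20,  # of grants, unspecified diagnosis
      secretagogue_fraction = 0.40,   # cases on insulin-secretion drugs (A10BB)
      insulin_later_fraction = 0.15,  # cases adding insulin two years after onset
      insulin_equal_fraction = 0.05,  # cases on insulin from onset (age 40+ only)
      insulin_only_fraction = 0.01    # never-T2D persons on insulin alone
    ),
    obesity = list(
      prevalence = c(M = 0.25, F = 0.25),  # illustrative placeholder values
      rr_incidence = 3.0,
      rr_mortality = 1.5
    ),
    entrant_quintile_shares = rep(0.2, 5)
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Entries present in the file override the defaults; everything else keeps
#' its default value. A `seed` entry is mandatory.
#'
#' @param path Path to a YAML file.
#' @return Configuration list as from [default_config()].
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user$seed)) abort("config must specify a seed")
  cfg <- default_config(seed = user$seed)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  cfg <- merge_lists(cfg, user)
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  inc <- cfg$incidence; mort <- cfg$mortality
  probs <- c(inc$base, inc$peak, mort$decline_rate, inc$decline_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("probability-scale parameters must lie in [0, 1]")
  }
  if (length(inc$quintile_mult) != 5 || length(mort$quintile_mult) != 5) {
    abort("quintile multipliers must have length 5")
  }
  if (cfg$n_persons < 1) abort("n_persons must be positive")
  if (cfg$years[2] <= cfg$years[1]) abort("observation window must span > 1 year")
  invisible(cfg)
}
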