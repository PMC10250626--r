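clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

PROB_EPS <- 1e-8

GENDERS <- c("M", "F")
QUINTILES <- paste0("Q", 1:5)
AGE_MIN <- 30L
AGE_MAX <- 100L  # terminal age: both mortality probabilities forced to 1

quintile_index <- function(quintile) {
  i <- match(quintile, QUINTILES)
  if (anyNA(i)) abort("quintile labels must be Q1..Q5 (Q1 = highest income)")
  i
}

#' Five-year age stratum used for income ranking
#'
#' Ages 30+ are grouped as \[30,34\], \[35,39\], ..., \[95,99\], with a single
#' open-ended stratum at 100+.
#'
#' @param age Integer vector of ages (>= 30).
#' @return Integer code identifying the stratum (its lower bound).
#' @export
age_stratum_5y <- function(age) {
  stopifnot(all(age >= AGE_MIN, na.rm = TRUE))
  pmin(AGE_MIN + 5L * ((as.integer(age) - AGE_MIN) %/% 5L), 100L)
}

#' Ten-year age band used for calendar-trend fitting
#'
#' Bands 30-39, 40-49, ..., 80-89, 90-99; age 100 is the closed terminal age
#' and is excluded from trend fitting.
#'
#' @param age Integer vector of ages.
#' @return Band label, e.g. "30-39".
#' @export
age_band_10y <- function(age) {
  lo <- pmin(AGE_MIN + 10L * ((as.integer(age) - AGE_MIN) %/% 10L), 90L)
  paste0(lo, "-", lo + 9L)
}

# age bands as printed in prevalence tables: 30-39 ... 80-89, 90+
age_band_table <- function(age) {
  lo <- pmin(AGE_MIN + 10L * ((as.integer(age) - AGE_MIN) %/% 10L), 90L)
  ifelse(lo >= 90L, "90+", paste0(lo, "-", lo + 9L))
}

# empirical logit with a half-count continuity adjustment
elogit <- function(events, n) qlogis((events + 0.5) / (n + 1))

# canonical row order shared by every transition-probability producer,
# so that sets can be compared elementwise
arrange_probs <- function(probs) {
  arrange(probs, .data$year, .data$gender, .data$quintile, .data$age)
}

stage_error <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
  })
}
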