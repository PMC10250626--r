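#' Estimate annual transition probabilities from stratified counts
#'
#' Occurrence/exposure estimation within each age x gender x quintile x year
#' cell: `p_inc = n_incident / n_free`, `p_mF = n_death_free / n_free`,
#' `p_mT = n_death_t2d / n_t2d`. Empty cells are `NA` and are filled later by
#' [smooth_over_age()]. Because an incidence event in exposure year y is
#' only observable once the year y + 1 register entry is seen, `p_inc` is
#' structurally missing in the final register year.
#'
#' @param counts A `strata_counts` tibble from [aggregate_counts()].
#' @return A `transition_probs` tibble carrying the count columns alongside
#'   `p_inc`, `p_mF`, `p_mT`.
#' @export
estimate_transition_probabilities <- function(counts) {
  validate_strata_counts(counts)
  last_year <- max(counts$year)
  out <- counts |>
    mutate(
      p_inc = ifelse(.data$n_free > 0 & .data$year < last_year,
                     .data$n_incident / .data$n_free, NA_real_),
      p_mF = ifelse(.data$n_free > 0, .data$n_death_free / .data$n_free, NA_real_),
      p_mT = ifelse(.data$n_t2d > 0, .data$n_death_t2d / .data$n_t2d, NA_real_)
    ) |>
    arrange_probs()
  class(out) <- c("transition_probs", class(out))
  out
}

# transition -> (event, denominator) count columns
TRANSITION_COLS <- list(
  p_inc = c("n_incident", "n_free"),
  p_mF = c("n_death_free", "n_free"),
  p_mT = c("n_death_t2d", "n_t2d")
)

#' Smooth transition probabilities over age
#'
#' Within each gender x quintile x year stratum, each transition is smoothed
#' over age on the logit scale. With count columns present the fit is a
#' binomial natural-spline regression whose basis dimension scales with the
#' observed event count (so rare-event profiles get a near-linear logit fit,
#' and no empirical-logit continuity correction — which would bias rare
#' events upward — is needed); without counts a weighted smoothing spline
#' on the logit is used. Outside the observed age span the boundary value
#' is held constant. Cells observed with at least `min_n` at-risk persons
#' are kept at their raw estimate; sparse and missing cells take the
#' smoothed value, so the smoother acts as a stabilizer/interpolator rather
#' than a re-estimator of well-supported cells. The terminal age (100) is
#' closed: both mortality probabilities are set to 1 and incidence to 0.
#'
#' A fully missing age profile is an error, with one exception: `p_inc` in
#' the final year of the set is structurally censored (see
#' [estimate_transition_probabilities()]) and is left missing.
#'
#' @param probs A `transition_probs` tibble, with or without count columns.
#' @param min_n At-risk threshold above which raw estimates are kept.
#' @return A `transition_probs` tibble on the same grid.
#' @export
smooth_over_age <- function(probs, min_n = 500) {
  has_counts <- all(unlist(TRANSITION_COLS) %in% names(probs))
  last_year <- max(probs$year)
  out <- arrange_probs(probs)
  key <- paste(out$gender, out$quintile, out$year)
  groups <- split(seq_len(nrow(out)), key)

  for (idx in groups) {
    age <- out$age[idx]
    interior <- age < AGE_MAX
    for (tr in names(TRANSITION_COLS)) {
      p <- out[[tr]][idx]
      if (has_counts) {
        ev <- out[[TRANSITION_COLS[[tr]][1]]][idx]
        den <- out[[TRANSITION_COLS[[tr]][2]]][idx]
      } else {
        ev <- NULL
        den <- rep(1, length(idx))
      }
      obs <- interior & !is.na(p) & den > 0
      if (!any(obs)) {
        if (tr == "p_inc" && out$year[idx][1] == last_year) next
        abort(paste0("all-missing age profile for ", tr, " in stratum ",
                     out$gender[idx][1], "/", out$quintile[idx][1], "/",
                     out$year[idx][1]))
      }
      x <- age[obs]
      # prediction ages: interpolate inside the observed age span; hold the
      # boundary value outside it (logit-linear extrapolation is
      # unsupported by data)
      x_pred <- clamp(age[interior], min(x), max(x))
      sm <- if (has_counts && length(unique(x)) >= 5) {
        # exposure-weighted binomial regression spline on the logit scale;
        # unlike an empirical-logit transform this is unbiased for rare
        # events, and the fixed basis dimension keeps 100s of stratum-year
        # fits fast
        # basis dimension scales with the event count so that sparse
        # profiles get a near-linear logit fit instead of an oscillating one
        kk <- max(2L, min(6L, length(unique(x)) - 2L,
                          floor(sum(ev[obs]) / 10)))
        fit <- suppressWarnings(stats::glm(
          cbind(ev[obs], den[obs] - ev[obs]) ~ splines::ns(x, df = kk),
          family = stats::binomial()
        ))
        as.numeric(predict(fit, newdata = data.frame(x = x_pred)))
      } else {
        y <- if (has_counts) elogit(ev[obs], den[obs]) else {
          qlogis(clamp(p[obs], PROB_EPS, 1 - PROB_EPS))
        }
        if (length(unique(x)) >= 4) {
          fit <- smooth.spline(x, y, w = den[obs])
          predict(fit, x_pred)$y
        } else {
          approx(x, y, xout = x_pred, rule = 2, ties = mean)$y
        }
      }
      p_new <- p
      p_new[interior] <- clamp(plogis(sm), PROB_EPS, 1 - PROB_EPS)
      keep_raw <- obs & (!has_counts | den >= min_n)
      p_new[keep_raw] <- p[keep_raw]
      out[[tr]][idx] <- p_new
    }
    terminal <- idx[age == AGE_MAX]
    out$p_mF[terminal] <- 1
    out$p_mT[terminal] <- 1
    out$p_inc[terminal] <- 0
  }
  enforce_row_constraints(out)
}

# proportional rescale so that p_inc + p_mF <= 0.999 where both are present
enforce_row_constraints <- function(probs) {
  s <- probs$p_inc + probs$p_mF
  bad <- !is.na(s) & s > 1
  if (any(bad)) {
    f <- 0.999 / s[bad]
    probs$p_inc[bad] <- probs$p_inc[bad] * f
    probs$p_mF[bad] <- probs$p_mF[bad] * f
    inform(paste0("rescaled p_inc + p_mF > 1 in ", sum(bad), " cells"))
  }
  if (!inherits(probs, "transition_probs")) {
    class(probs) <- c("transition_probs", class(probs))
  }
  probs
}

# ---------------------------------------------------------------------------
# calendar-trend machinery

# age-level series of one transition family: per gender x quintile x band x
# single age x year, either event/exposure counts or a probability with a
# weight. Keeping single ages lets the slope models adjust for age
# composition drifting within a band over calendar time.
band_series <- function(probs, years, kind = c("mortality", "incidence")) {
  kind <- match.arg(kind)
  df <- probs |> filter(.data$year %in% years, .data$age < AGE_MAX)
  df$band <- age_band_10y(df$age)
  has_counts <- all(unlist(TRANSITION_COLS) %in% names(df))
  if (has_counts) {
    # the calendar trend is fit to non-T2D outcomes: with the T2D
    # differential frozen one common trend drives both states, and the
    # disease-free group is unconfounded by the rising T2D share
    ev_col <- if (kind == "mortality") "n_death_free" else "n_incident"
    df |>
      filter(.data$n_free > 0) |>
      transmute(
        .data$gender, .data$quintile, .data$band, .data$age, .data$year,
        events = .data[[ev_col]], expo = .data$n_free
      )
  } else {
    col <- if (kind == "mortality") "p_mF" else "p_inc"
    df |>
      filter(!is.na(.data[[col]])) |>
      transmute(.data$gender, .data$quintile, .data$band, .data$age,
                .data$year, m = .data[[col]], w = 1)
  }
}

# age-adjusted annual log-scale slope of one series (single stratum or a
# pooled set). Composition drift across the pooled age cells is removed by
# indirect standardization: count data are collapsed to a yearly
# standardized ratio, observed events over those expected from each cell's
# all-years reference rate; probability data to the yearly mean log
# deviation from each cell's all-years log level. For long windows the
# calendar effect is a penalized spline and the reported slope is the
# least-squares slope of the fitted effect over the final decade; short
# windows are log-linear.
fit_log_slope <- function(df) {
  has_counts <- "events" %in% names(df)
  df$cell <- paste(
    if ("gender" %in% names(df)) df$gender else "",
    df$quintile, df$band, df$age
  )
  if (length(unique(df$year)) < 2) return(0)
  series <- if (has_counts) {
    ref <- df |>
      group_by(.data$cell) |>
      summarise(rate = sum(.data$events) / sum(.data$expo), .groups = "drop")
    df |>
      left_join(ref, by = "cell") |>
      group_by(.data$year) |>
      summarise(
        y = log((sum(.data$events) + 0.5) /
                  (sum(.data$expo * .data$rate) + 0.5)),
        w = sum(.data$expo * .data$rate),
        .groups = "drop"
      ) |>
      filter(is.finite(.data$y), .data$w > 0)
  } else {
    df$y0 <- log(pmax(df$m, PROB_EPS))
    df |>
      group_by(.data$cell) |>
      mutate(y0 = .data$y0 - mean(.data$y0)) |>
      group_by(.data$year) |>
      summarise(y = weighted.mean(.data$y0, .data$w), w = sum(.data$w),
                .groups = "drop")
  }
  ny <- nrow(series)
  if (ny < 2) return(0)
  slope <- tryCatch({
    if (ny >= 12) {
      k <- min(8, ny - 2)
      fit <- mgcv::gam(y ~ s(year, k = k), weights = w, data = series)
      fv <- as.numeric(predict(fit, newdata = series["year"]))
      tail_idx <- series$year > max(series$year) - 10
      unname(coef(lm(fv[tail_idx] ~ series$year[tail_idx]))[2])
    } else {
      unname(coef(lm(y ~ year, data = series, weights = series$w))["year"])
    }
  }, error = function(e) NA_real_)
  if (!is.finite(slope)) {
    inform("smooth trend fit failed; falling back to a log-linear fit")
    slope <- tryCatch(
      unname(coef(lm(y ~ year, data = series, weights = series$w))["year"]),
      error = function(e) 0
    )
    if (!is.finite(slope)) slope <- 0
  }
  slope
}

# slopes per stratum under the requested pooling level; pooled fits share a
# common year slope across strata with stratum-specific (age-level) levels
band_slopes <- function(series, pool = c("band", "gender", "global")) {
  pool <- match.arg(pool)
  strata <- distinct(series, .data$gender, .data$quintile, .data$band)
  sl <- switch(pool,
    band = series |>
      group_by(.data$gender, .data$quintile, .data$band) |>
      group_modify(\(df, key) tibble(slope = fit_log_slope(df))) |>
      ungroup(),
    gender = series |>
      group_by(.data$gender) |>
      group_modify(\(df, key) tibble(slope = fit_log_slope(df))) |>
      ungroup(),
    global = tibble(slope = fit_log_slope(series))
  )
  if (pool == "global") return(mutate(strata, slope = sl$slope))
  by_cols <- intersect(c("gender", "quintile", "band"), names(sl))
  left_join(strata, sl, by = by_cols)
}

#' Project mortality trends, freezing T2D differentials
#'
#' Fits a smooth declining (or flat) calendar trend on the log scale to
#' age-standardized disease-free mortality in `fit_years` — a penalized
#' spline on calendar year for long windows, log-linear for short ones —
#' and extrapolates it log-linearly over `target_years`. Age
#' standardization (yearly observed over expected events, with expected
#' events from each age cell's all-years reference rate) removes the bias
#' from age composition drifting within bands over calendar time, and the
#' disease-free series avoids the confounding of total mortality by the
#' rising T2D share. The projected probabilities are the anchor-year age
#' profiles of `p_mF` and `p_mT` scaled by the common trend factor, so the
#' T2D vs non-T2D mortality ratio and the income differentials are frozen
#' at their end-of-history (2019-level) values by construction. The
#' terminal age stays closed at probability 1.
#'
#' @param probs A `transition_probs` tibble covering `fit_years` (ideally
#'   smoothed; counts used as weights when present).
#' @param fit_years Historical years used for fitting.
#' @param target_years Years to project; must start after `fit_years`.
#' @param pool Pooling level for the year slope: shared per `"gender"`
#'   (default), per `"band"` (gender x quintile x 10-year age band), or one
#'   `"global"` slope. Stratum-specific anchors keep all age, income and
#'   T2D differentials under any pooling; pooling only stabilizes the
#'   22-year extrapolation of the calendar slope, whose stratum-level noise
#'   otherwise dominates the projection horizon.
#' @return A `transition_probs` tibble with historical rows unchanged and
#'   projected rows appended (`p_inc` is `NA` until a scenario rule fills
#'   it). The slope table is attached as attribute `"trend"`.
#' @export
fit_mortality_trend <- function(probs, fit_years = 1995:2018,
                                target_years = 2019:2040,
                                pool = c("gender", "band", "global")) {
  pool <- match.arg(pool)
  obs_years <- intersect(fit_years, unique(probs$year))
  if (length(obs_years) < 2) abort("need at least two historical years to fit")
  series <- band_series(probs, obs_years, kind = "mortality")
  slopes <- band_slopes(series, pool)
  anchor_year <- max(obs_years)
  target_years <- target_years[target_years > anchor_year]

  anchor <- probs |>
    filter(.data$year == anchor_year) |>
    select("age", "gender", "quintile", "p_mF", "p_mT", "p_inc")
  anchor$band <- age_band_10y(anchor$age)
  anchor <- left_join(anchor, slopes, by = c("gender", "quintile", "band"))
  anchor$slope[is.na(anchor$slope)] <- 0

  proj <- expand_grid(anchor, year = target_years) |>
    mutate(
      fac = exp(.data$slope * (.data$year - anchor_year)),
      p_mF = clamp(.data$p_mF * .data$fac, PROB_EPS, 1 - PROB_EPS),
      p_mT = clamp(.data$p_mT * .data$fac, PROB_EPS, 1 - PROB_EPS),
      p_inc = NA_real_
    ) |>
    mutate(
      p_mF = ifelse(.data$age == AGE_MAX, 1, .data$p_mF),
      p_mT = ifelse(.data$age == AGE_MAX, 1, .data$p_mT)
    ) |>
    select("age", "gender", "quintile", "year", "p_inc", "p_mF", "p_mT")

  hist <- probs |> filter(.data$year <= anchor_year)
  out <- bind_rows(hist, proj) |>
    arrange(.data$year, .data$gender, .data$quintile, .data$age)
  attr(out, "trend") <- slopes
  enforce_row_constraints(out)
}

#' Project the post-2011 declining incidence trend (scenario A)
#'
#' Fits a log-scale calendar trend to band-aggregated T2D incidence on the
#' fit window starting at `trend_from`, never using `exclude_years` (the
#' diagnosis-campaign bump years), and extrapolates it over `target_years`
#' from the last fitted year's age profiles. A fitted *rising* trend is
#' allowed but flagged with a warning as a deviation from the expected
#' decline. Because the post-exclusion window is short, the year slope is
#' pooled per gender by default while anchors stay fully stratum-specific,
#' preserving age and income differentials.
#'
#' @param probs A `transition_probs` tibble with projected mortality rows
#'   (from [fit_mortality_trend()]); its historical `p_inc` is used.
#' @param trend_from First calendar year of the fit window.
#' @param exclude_years Years never used for fitting.
#' @param target_years Years whose `p_inc` is filled.
#' @param pool Pooling level for the year slope (see
#'   [fit_mortality_trend()]); default `"gender"`.
#' @return A `transition_probs` tibble with `p_inc` filled for
#'   `target_years`; slope table attached as attribute `"incidence_trend"`.
#' @export
fit_incidence_trend <- function(probs, trend_from = 2011,
                                exclude_years = 2007:2010,
                                target_years = 2019:2040,
                                pool = c("gender", "band", "global")) {
  pool <- match.arg(pool)
  with_inc <- unique(probs$year[!is.na(probs$p_inc)])
  fit_years <- setdiff(with_inc[with_inc >= trend_from], exclude_years)
  if (length(fit_years) < 2) {
    abort("incidence fit window is empty (or a single year) after exclusions")
  }
  series <- band_series(probs |> filter(.data$year %in% fit_years),
                        fit_years, kind = "incidence")
  slopes <- band_slopes(series, pool)
  if (any(slopes$slope > 0)) {
    warn("fitted incidence trend is rising in some strata, not declining")
  }
  anchor_year <- max(fit_years)
  target_years <- target_years[target_years > anchor_year]

  anchor <- probs |>
    filter(.data$year == anchor_year) |>
    select("age", "gender", "quintile", anchor_inc = "p_inc")
  anchor$band <- age_band_10y(anchor$age)
  anchor <- left_join(anchor, slopes, by = c("gender", "quintile", "band"))
  anchor$slope[is.na(anchor$slope)] <- 0

  fill <- expand_grid(anchor, year = target_years) |>
    mutate(p_inc_new = clamp(
      .data$anchor_inc * exp(.data$slope * (.data$year - anchor_year)), 0, 1
    )) |>
    select("age", "gender", "quintile", "year", "p_inc_new")

  out <- probs |>
    left_join(fill, by = c("age", "gender", "quintile", "year")) |>
    mutate(p_inc = ifelse(.data$year > anchor_year & !is.na(.data$p_inc_new),
                          .data$p_inc_new, .data$p_inc)) |>
    select(-"p_inc_new")
  # target years absent from the input (no mortality projection yet) are
  # appended with the projected incidence alone
  new_years <- setdiff(target_years, unique(probs$year))
  if (length(new_years)) {
    extra <- fill |>
      filter(.data$year %in% new_years) |>
      rename(p_inc = "p_inc_new") |>
      mutate(p_mF = NA_real_, p_mT = NA_real_)
    out <- bind_rows(out, extra) |> arrange_probs()
  }
  attr(out, "incidence_trend") <- slopes
  enforce_row_constraints(out)
}

#' Hold T2D incidence constant after a reference year (baseline scenario)
#'
#' Sets `p_inc` in every year after the anchor to its anchor-year value in
#' each stratum, leaving mortality untouched. The anchor is the latest year
#' not after `at_year` with estimable incidence; with a register observed
#' through 2019 that is exposure year 2018, i.e. the schedule producing
#' register entries in 2019 — the "2019 level". Idempotent.
#'
#' @param probs A `transition_probs` tibble (typically with projected
#'   mortality rows whose `p_inc` is still `NA`).
#' @param at_year Reference year whose incidence level is carried forward.
#' @return A `transition_probs` tibble with constant future `p_inc`.
#' @export
hold_incidence_constant <- function(probs, at_year = 2019) {
  with_inc <- unique(probs$year[!is.na(probs$p_inc)])
  with_inc <- with_inc[with_inc <= at_year]
  if (length(with_inc) == 0) abort("no estimable incidence at or before at_year")
  anchor_year <- max(with_inc)
  anchor <- probs |>
    filter(.data$year == anchor_year) |>
    select("age", "gender", "quintile", anchor_inc = "p_inc")
  out <- probs |>
    left_join(anchor, by = c("age", "gender", "quintile")) |>
    mutate(p_inc = ifelse(.data$year > anchor_year, .data$anchor_inc,
                          .data$p_inc)) |>
    select(-"anchor_inc")
  enforce_row_constraints(out)
}

#' Read/write a transition-probability set as tidy CSV
#'
#' Columns (age, gender, quintile, year, p_inc, p_mF, p_mT); the round trip
#' is lossless to at least 12 significant digits.
#'
#' @param probs A `transition_probs` tibble.
#' @param path File path.
#' @return `read_transition_probs()` returns the `transition_probs` tibble.
#' @export
write_transition_probs <- function(probs, path) {
  df <- probs[c("age", "gender", "quintile", "year", "p_inc", "p_mF", "p_mT")]
  for (col in c("p_inc", "p_mF", "p_mT")) {
    df[[col]] <- formatC(df[[col]], digits = 15, format = "g")
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_transition_probs
#' @export
read_transition_probs <- function(path) {
  out <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  for (col in c("p_inc", "p_mF", "p_mT")) out[[col]] <- as.numeric(out[[col]])
  class(out) <- c("transition_probs", class(out))
  out
}
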