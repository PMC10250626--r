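#' Compare a model series against a reference series
#'
#' Computes the absolute percentage error per overlapping year, the mean
#' and maximum APE, and a pass flag against a configurable MAPE threshold.
#' The reference can be a CSV file shaped like published life-table or
#' count series — columns (year, value) — or a data frame; nothing is ever
#' downloaded.
#'
#' @param model_series Tibble with columns `year` and `value`.
#' @param reference Path to a CSV with columns (year, value), or a tibble.
#' @param threshold MAPE pass threshold as a proportion (default 0.05).
#' @param label Optional source label carried into the report.
#' @return A `t2d_validation` list: `per_year` tibble (year, model,
#'   reference, ape), `mape`, `max_ape`, `n_years`, `threshold`, `pass`,
#'   `source`.
#' @export
validate_against_reference <- function(model_series, reference,
                                       threshold = 0.05, label = NULL) {
  if (is.character(reference)) {
    label <- label %||% basename(reference)
    reference <- as_tibble(read.csv(reference, stringsAsFactors = FALSE))
  }
  stopifnot(all(c("year", "value") %in% names(model_series)),
            all(c("year", "value") %in% names(reference)))
  joined <- inner_join(
    select(model_series, "year", model = "value"),
    select(reference, "year", reference = "value"),
    by = "year"
  )
  if (nrow(joined) == 0) abort("no overlapping years between model and reference")
  joined$ape <- abs(joined$model - joined$reference) / abs(joined$reference)
  out <- list(
    per_year = joined,
    mape = mean(joined$ape),
    max_ape = max(joined$ape),
    n_years = nrow(joined),
    threshold = threshold,
    pass = mean(joined$ape) <= threshold,
    source = label %||% "reference"
  )
  class(out) <- "t2d_validation"
  out
}

#' @export
print.t2d_validation <- function(x, ...) {
  cat(sprintf(
    "<t2d_validation> %s: MAPE %.2f%% (max %.2f%%) over %d years -- %s\n",
    x$source, 100 * x$mape, 100 * x$max_ape, x$n_years,
    if (x$pass) "PASS" else "FAIL"
  ))
  invisible(x)
}

#' Run the full projection pipeline
#'
#' Executes generate -> ascertain -> quintile assignment -> aggregate ->
#' estimate/smooth -> scenario construction -> projection -> prevalence and
#' health-expectancy tables -> validation, and optionally writes all
#' outputs plus a reproducibility manifest to a directory. Idempotent for a
#' fixed configuration and seed.
#'
#' @param config Configuration list, see [default_config()] /
#'   [read_config()].
#' @param scenarios Subset of `c("baseline", "A", "B", "C")` to project.
#' @param prevalence_years Years tabulated in the prevalence tables.
#' @param le_years Years evaluated in the health expectancy tables.
#' @param out_dir Optional output directory (created if missing).
#' @param write_register Also write the full person-year register CSV
#'   (large) when `out_dir` is given.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with all intermediate and final objects:
#'   register, ascertainment, quintiles, counts, probs, paf, scenarios,
#'   initial, entrants, trajectories, prevalence, health_expectancy,
#'   inequality, validation, manifest.
#' @export
run_pipeline <- function(config = default_config(),
                         scenarios = c("baseline", "A", "B", "C"),
                         prevalence_years = c(2020, 2030, 2040),
                         le_years = c(2020, 2040),
                         out_dir = NULL, write_register = FALSE,
                         quiet = TRUE) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  say <- function(...) if (!quiet) inform(paste0(...))
  horizon <- config$horizon
  start_year <- config$years[2]

  say("generating synthetic register (n = ", config$n_persons, ")")
  reg <- stage_error("generate", generate_register(config))
  register <- reg$register

  say("ascertaining T2D")
  ascertainment <- stage_error("ascertain", ascertain_register(register))

  say("assigning income quintiles at cohort entry")
  quintiles <- stage_error("quintiles", {
    entry <- register |>
      group_by(.data$person_id) |>
      summarise(entry_year = min(.data$year), .groups = "drop")
    per_year <- lapply(sort(unique(entry$entry_year)), function(y) {
      assign_income_quintiles(register, y) |>
        semi_join(filter(entry, .data$entry_year == y), by = "person_id")
    })
    bind_rows(per_year)
  })

  say("aggregating person-years")
  counts <- stage_error("aggregate", aggregate_counts(register, ascertainment,
                                                      quintiles))

  say("estimating and smoothing transition probabilities")
  probs <- stage_error("estimate", {
    smooth_over_age(estimate_transition_probabilities(counts))
  })

  say("building scenarios")
  scen_sets <- stage_error("scenarios", build_all_scenarios(
    probs, assumptions = config$obesity,
    fit_years = config$years[1]:(start_year - 1),
    target_years = start_year:horizon
  ))
  paf <- attr(scen_sets, "paf")

  say("projecting ", start_year, " -> ", horizon)
  init <- stage_error("initial_state", initial_state(register, ascertainment,
                                                     quintiles, start_year))
  entrants <- stage_error("entrants", entrant_schedule(
    (start_year + 1):horizon, register = register,
    quintile_shares = config$entrant_quintile_shares
  ))
  trajectories <- lapply(scenarios, function(s) {
    stage_error(paste0("project_", s), project_population(
      init, scen_sets[[s]], entrants, start_year = start_year,
      horizon = horizon
    ))
  })
  names(trajectories) <- scenarios

  say("tabulating prevalence and health expectancy")
  prevalence <- lapply(trajectories, prevalence_table,
                       years = prevalence_years)
  het <- lapply(scenarios, function(s) {
    stage_error(paste0("le_", s), health_expectancy_table(
      trajectories[[s]], scen_sets[[s]], years = le_years
    ))
  })
  names(het) <- scenarios
  inequality <- lapply(het, inequality_summary)

  say("validating against ground truth")
  validation <- stage_error("validate", {
    truth_prev <- truth_prevalence_series(reg$truth$persons, register)
    model_prev <- register |>
      left_join(select(ascertainment, "person_id", "incidence_year"),
                by = "person_id") |>
      filter(!is.na(.data$incidence_year),
             .data$year >= .data$incidence_year) |>
      count(.data$year, name = "value")
    deaths_obs <- counts |>
      group_by(.data$year) |>
      summarise(value = sum(.data$n_death_free + .data$n_death_t2d),
                .groups = "drop")
    deaths_exp <- counts |>
      inner_join(reg$truth$schedule,
                 by = c("age", "gender", "quintile", "year")) |>
      group_by(.data$year) |>
      summarise(value = sum(.data$n_free * .data$p_mF +
                              .data$n_t2d * .data$p_mT), .groups = "drop")
    list(
      prevalence = validate_against_reference(
        model_prev, truth_prev, label = "ground-truth prevalence"
      ),
      deaths = validate_against_reference(
        deaths_obs, deaths_exp, label = "ground-truth expected deaths"
      )
    )
  })

  manifest <- list(
    package = "t2dms",
    version = as.character(packageVersion("t2dms")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    scenarios = scenarios,
    n_persons = config$n_persons,
    horizon = horizon,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )

  result <- list(
    register = register, truth = reg$truth, ascertainment = ascertainment,
    quintiles = quintiles, counts = counts, probs = probs, paf = paf,
    scenarios = scen_sets[scenarios], initial = init, entrants = entrants,
    trajectories = trajectories, prevalence = prevalence,
    health_expectancy = het, inequality = inequality,
    validation = validation, manifest = manifest, config = config
  )
  class(result) <- "t2d_pipeline"

  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir, write_register = write_register)
  }
  invisible(result)
}

# true prevalent-case counts per register year from the generator truth
truth_prevalence_series <- function(persons, register) {
  years <- sort(unique(register$year))
  counts <- vapply(years, function(y) {
    sum(!is.na(persons$t_inc) & persons$t_inc <= y &
          (is.na(persons$death_year) | persons$death_year >= y) &
          persons$entry_year <= y)
  }, numeric(1))
  tibble(year = years, value = counts)
}

write_pipeline_outputs <- function(result, out_dir, write_register = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  if (write_register) write_register_csv(result$register, p("register.csv"))
  write_strata_counts(result$counts, p("strata_counts.csv"))
  write.csv(result$paf, p("paf.csv"), row.names = FALSE)
  for (s in names(result$scenarios)) {
    write_transition_probs(result$scenarios[[s]],
                           p(paste0("transition_probs_", s, ".csv")))
    write.csv(result$trajectories[[s]], p(paste0("trajectory_", s, ".csv")),
              row.names = FALSE)
    write.csv(result$prevalence[[s]], p(paste0("prevalence_", s, ".csv")),
              row.names = FALSE)
    write.csv(result$health_expectancy[[s]],
              p(paste0("health_expectancy_", s, ".csv")), row.names = FALSE)
    write.csv(result$inequality[[s]], p(paste0("inequality_", s, ".csv")),
              row.names = FALSE)
  }
  val <- tibble(
    series = names(result$validation),
    mape = vapply(result$validation, function(v) v$mape, numeric(1)),
    max_ape = vapply(result$validation, function(v) v$max_ape, numeric(1)),
    n_years = vapply(result$validation, function(v) v$n_years, numeric(1)),
    pass = vapply(result$validation, function(v) v$pass, logical(1))
  )
  write.csv(val, p("validation.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.t2d_pipeline <- function(x, ...) {
  cat("<t2d_pipeline>\n")
  cat("  seed:", x$config$seed, " persons:", x$config$n_persons, "\n")
  cat("  scenarios:", paste(names(x$trajectories), collapse = ", "), "\n")
  all_row <- x$prevalence[[1]][x$prevalence[[1]]$group == "All", ]
  cat("  prevalent cases (", names(x$prevalence)[1], "): ",
      paste(sprintf("%s=%d", sub("cases_", "", names(all_row)[grep("^cases_",
        names(all_row))]), round(unlist(all_row[grep("^cases_",
        names(all_row))]))), collapse = ", "), "\n", sep = "")
  invisible(x)
}
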