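#' Pipeline run configuration
#'
#' Either a `simulate` block (region + simulator settings, for a fully
#' synthetic run) or `paths` to existing `incidents.csv` / `missions.csv`
#' logs — never both. All the analysis constants live here: 15 km neighbor
#' radius, 5000 max neighbors, up to 5 candidate units, the strict 10%
#' candidate threshold, the 50-neighbor minimum, and the bootstrap size.
#'
#' @param simulate Optional list: `n_stations`, `n_neighbourhoods`,
#'   `urban_fraction`, plus any [sim_config()] argument.
#' @param paths Optional list with `incidents` and `missions` paths.
#' @param radius_km,max_neighbors,max_units,threshold,min_neighbors
#'   Candidate-model and exposure settings.
#' @param bootstrap_b Bayesian bootstrap replicates.
#' @param seed Master seed (mandatory; drives simulation and bootstrap).
#' @param strata Stratification families for [stratified_estimates()].
#' @param balance Run the incident-type balance test (logical).
#' @param covid Run the pandemic-years sensitivity analysis (logical).
#' @return A list of class `ambusy_run_config`.
#' @export
run_config <- function(simulate = NULL, paths = NULL,
                       radius_km = 15, max_neighbors = 5000,
                       max_units = 5, threshold = 0.10,
                       min_neighbors = 50, bootstrap_b = 200,
                       seed = 1L, strata = c("overall", "urban",
                                             "candidates"),
                       balance = FALSE, covid = FALSE) {
  if (is.null(simulate) == is.null(paths)) {
    abort("exactly one of `simulate` or `paths` must be given.",
          class = "ambusy_config_error")
  }
  if (any(c(radius_km, max_neighbors, max_units, threshold, min_neighbors,
            bootstrap_b) <= 0)) {
    abort("all numeric settings must be positive.",
          class = "ambusy_config_error")
  }
  if (is.null(seed)) {
    abort("seed is mandatory.", class = "ambusy_config_error")
  }
  structure(list(simulate = simulate, paths = paths, radius_km = radius_km,
                 max_neighbors = max_neighbors, max_units = max_units,
                 threshold = threshold, min_neighbors = min_neighbors,
                 bootstrap_b = bootstrap_b, seed = as.integer(seed),
                 strata = strata, balance = balance, covid = covid),
            class = "ambusy_run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [run_config()] arguments.
#' @return An `ambusy_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the full busy-ambulance pipeline
#'
#' Executes simulate (or load) -> ingest/filter -> candidate models ->
#' busy exposure -> delay estimation, writes the artifacts to `out_dir`
#' (exposure table, estimates CSV, results JSON, exclusion tally, JSON-line
#' log, manifest with config hash and seed) and returns the run report.
#' Re-running with an identical config and seed reproduces identical
#' results.
#'
#' @param config An `ambusy_run_config` (or YAML path).
#' @param out_dir Output directory.
#' @return Invisibly, a list with `eligible`, `exposure`, `rows`,
#'   `estimates`, `tally`, `manifest` (plus `balance`/`covid` when
#'   enabled and `ground_truth` for simulated runs).
#' @export
run_ems_pipeline <- function(config, out_dir = tempfile("ambusy_run_")) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "ambusy_run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  log_line <- function(stage, ...) {
    rec <- c(list(stage = stage, time = format(Sys.time(), "%H:%M:%S")),
             list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      log_line(name, status = "error", message = conditionMessage(e))
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "ambusy_stage_error", parent = e)
    })
    log_line(name, status = "ok",
             seconds = round(proc.time()[["elapsed"]] - t0, 2))
    res
  }

  sim_tables <- stage("input", {
    if (!is.null(config$simulate)) {
      sb <- config$simulate
      region <- generate_region(
        n_stations = sb$n_stations %||% 10,
        n_neighbourhoods = sb$n_neighbourhoods %||% 40,
        urban_fraction = sb$urban_fraction %||% 0.3,
        seed = config$seed)
      cfg_args <- sb[setdiff(names(sb),
                             c("n_stations", "n_neighbourhoods",
                               "urban_fraction"))]
      cfg_args$seed <- config$seed
      sim <- simulate_operations(region, do.call(sim_config, cfg_args))
      inc <- inject_defects(sim$incidents, sim$config, seed = config$seed)
      list(incidents = inc, missions = sim$missions,
           ground_truth = sim$ground_truth)
    } else {
      list(incidents = read_incidents(config$paths$incidents),
           missions = read_missions(config$paths$missions),
           ground_truth = NULL)
    }
  })
  ground_truth <- sim_tables$ground_truth

  filtered <- stage("filter", filter_incidents(sim_tables$incidents))
  exposure <- stage("exposure", estimate_busy_exposure(
    filtered$eligible, sim_tables$missions,
    radius_km = config$radius_km, max_neighbors = config$max_neighbors,
    max_units = config$max_units, min_neighbors = config$min_neighbors,
    threshold = config$threshold))
  rows <- stage("analysis_rows", analysis_rows(filtered$eligible, exposure))
  estimates <- stage("estimates", stratified_estimates(
    rows, B = config$bootstrap_b, seed = config$seed,
    strata = config$strata))
  balance <- if (isTRUE(config$balance)) {
    stage("balance", balance_test(rows, B = config$bootstrap_b,
                                  seed = config$seed))
  }
  covid <- if (isTRUE(config$covid)) {
    stage("covid", covid_sensitivity(rows, B = config$bootstrap_b,
                                     seed = config$seed))
  }

  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    n_input = filtered$tally$input,
    n_eligible = filtered$tally$eligible,
    n_exposure_ok = sum(exposure$status == "ok"),
    n_analysis = nrow(rows)
  )
  stage("write", {
    flat_exposure <- exposure |>
      dplyr::mutate(
        candidates = purrr::map2_chr(.data$units, .data$probs, function(u, p) {
          if (!length(u)) return("")
          paste(sprintf("%s:%.6f", u, p), collapse = ";")
        }),
        busy_units = purrr::map2_chr(.data$units, .data$busy, function(u, b) {
          paste(u[as.logical(b)], collapse = ";")
        })) |>
      dplyr::select(-dplyr::all_of(c("units", "probs", "busy")))
    readr::write_csv(flat_exposure, file.path(out_dir, "exposure.csv"))
    readr::write_csv(estimates, file.path(out_dir, "estimates.csv"))
    jsonlite::write_json(unclass(filtered$tally),
                         file.path(out_dir, "exclusion_tally.json"),
                         auto_unbox = TRUE)
    jsonlite::write_json(
      list(manifest = manifest,
           estimates = as.data.frame(estimates),
           balance = if (!is.null(balance)) as.data.frame(balance),
           covid = if (!is.null(covid)) as.data.frame(covid)),
      file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA)
    TRUE
  })

  invisible(list(eligible = filtered$eligible, exposure = exposure,
                 rows = rows, estimates = estimates, tally = filtered$tally,
                 balance = balance, covid = covid,
                 ground_truth = ground_truth, manifest = manifest,
                 out_dir = out_dir))
}
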