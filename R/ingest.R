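incident_columns <- c("incident_id", "call_time", "lat", "lon", "urgency",
                      "incident_type", "nb_id", "urban", "unit_id",
                      "arrival_time", "mission_kind")
mission_columns <- c("mission_id", "unit_id", "start_time", "end_time",
                     "kind", "incident_id")

#' Read an incident log
#'
#' Reads a headered, comma-delimited incident table with ISO-8601 minute
#' timestamps into a typed tibble. Blank coordinates are legal and become
#' `NA` (they are removed later by [filter_incidents()]); malformed
#' timestamps and unknown urgency/type/kind values are reported with their
#' row numbers — as an error by default, or collected and skipped in
#' lenient mode.
#'
#' @param path CSV path.
#' @param lenient If `TRUE`, unparseable rows are dropped with a warning
#'   instead of an error.
#' @return A tibble of incident records; the problem report (if any) is
#'   attached as attribute `"problems"`.
#' @export
read_incidents <- function(path, lenient = FALSE) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(incident_columns, names(raw))
  if (length(missing_cols)) {
    abort(paste0("incident file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ambusy_schema_error")
  }
  out <- tibble(
    incident_id = raw$incident_id,
    call_time = parse_minute(raw$call_time),
    lat = suppressWarnings(as.numeric(raw$lat)),
    lon = suppressWarnings(as.numeric(raw$lon)),
    urgency = raw$urgency,
    incident_type = raw$incident_type,
    nb_id = raw$nb_id,
    urban = as.logical(raw$urban),
    unit_id = raw$unit_id,
    arrival_time = parse_minute(raw$arrival_time),
    mission_kind = raw$mission_kind
  )
  problems <- character(0)
  bad <- which(is.na(out$call_time) |
                 (is.na(out$arrival_time) & !is.na(raw$arrival_time) &
                    raw$arrival_time != ""))
  if (length(bad)) {
    problems <- c(problems, sprintf("row %d: malformed timestamp", bad))
  }
  bad_voc <- which(!out$urgency %in% urgency_levels |
                     !out$incident_type %in% incident_types |
                     !out$mission_kind %in% c("primary", "secondary"))
  if (length(bad_voc)) {
    problems <- c(problems,
                  sprintf("row %d: unknown urgency/type/kind value", bad_voc))
  }
  report_problems(out, problems, sort(unique(c(bad, bad_voc))), lenient)
}

#' Read a mission log
#'
#' @inheritParams read_incidents
#' @return A tibble of mission records (`mission_id`, `unit_id`,
#'   `start_time`, `end_time`, `kind`, `incident_id`).
#' @export
read_missions <- function(path, lenient = FALSE) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(mission_columns, names(raw))
  if (length(missing_cols)) {
    abort(paste0("mission file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ambusy_schema_error")
  }
  out <- tibble(
    mission_id = raw$mission_id,
    unit_id = raw$unit_id,
    start_time = parse_minute(raw$start_time),
    end_time = parse_minute(raw$end_time),
    kind = raw$kind,
    incident_id = raw$incident_id
  )
  problems <- character(0)
  bad <- which(is.na(out$start_time) | is.na(out$end_time) |
                 out$end_time <= out$start_time |
                 is.na(out$unit_id) | out$unit_id == "" |
                 !out$kind %in% c("primary", "secondary"))
  if (length(bad)) {
    problems <- sprintf("row %d: malformed mission record", bad)
  }
  report_problems(out, problems, bad, lenient)
}

report_problems <- function(out, problems, bad_rows, lenient) {
  if (length(problems)) {
    if (lenient) {
      warn(paste0("skipped ", length(bad_rows), " malformed row(s):\n",
                  paste(head(problems, 10), collapse = "\n")))
      out <- out[setdiff(seq_len(nrow(out)), bad_rows), , drop = FALSE]
      attr(out, "problems") <- problems
    } else {
      abort(paste0("malformed input rows:\n",
                   paste(head(problems, 10), collapse = "\n")),
            class = "ambusy_parse_error")
    }
  }
  out
}

#' Response time in whole minutes
#'
#' The difference between the time of the incident (first call) and the
#' arrival of the first responding ambulance on scene. Negative values are
#' returned as-is (the eligibility filter removes them); a missing arrival
#' gives `NA`.
#'
#' @param records Incident tibble with `call_time` and `arrival_time`.
#' @return Numeric vector of minutes.
#' @export
response_time_minutes <- function(records) {
  as.numeric(difftime(records$arrival_time, records$call_time,
                      units = "mins"))
}

#' Eligibility filter for incident records
#'
#' Keeps incidents that are primary missions, triaged acute, have
#' coordinates, and have a response time between 0 and 360 minutes
#' inclusive (negative or longer-than-six-hour response times are treated
#' as timestamp errors). Every input row is tallied under exactly one
#' reason, attributed in filter order: secondary, then non-acute, then
#' missing coordinates, then bad response time.
#'
#' @param records Incident tibble.
#' @return List with `eligible` (tibble) and `tally` (class
#'   `ambusy_exclusion_tally`: named counts plus input/eligible totals).
#' @export
filter_incidents <- function(records) {
  rt <- response_time_minutes(records)
  is_secondary <- records$mission_kind != "primary"
  is_non_acute <- !is_secondary & records$urgency != "acute"
  is_missing <- !is_secondary & !is_non_acute &
    (is.na(records$lat) | is.na(records$lon))
  is_bad_rt <- !is_secondary & !is_non_acute & !is_missing &
    (is.na(rt) | rt < 0 | rt > 360)
  eligible <- records[!(is_secondary | is_non_acute | is_missing | is_bad_rt),
                      , drop = FALSE]
  tally <- structure(list(
    input = nrow(records),
    eligible = nrow(eligible),
    secondary = sum(is_secondary),
    non_acute = sum(is_non_acute),
    missing_coords = sum(is_missing),
    bad_response_time = sum(is_bad_rt)
  ), class = "ambusy_exclusion_tally")
  list(eligible = eligible, tally = tally)
}

#' @export
print.ambusy_exclusion_tally <- function(x, ...) {
  cat(sprintf(paste0(
    "<exclusion tally> %d records in -> %d eligible\n",
    "  secondary: %d | non-acute: %d | missing coords: %d | bad response time: %d\n"),
    x$input, x$eligible, x$secondary, x$non_acute, x$missing_coords,
    x$bad_response_time))
  invisible(x)
}

#' Urban/rural classification of neighbourhoods
#'
#' A neighbourhood is urban if it belongs to a densely populated area whose
#' total population exceeds 10,000 inhabitants (strictly).
#'
#' @param populations Tibble with `nb_id`, `area_id` (densely populated
#'   area membership; `NA` for neighbourhoods outside any such area) and
#'   `population`.
#' @return Tibble `nb_id`, `urban`.
#' @export
#' @examples
#' classify_urban(tibble::tibble(nb_id = c("a", "b"),
#'   area_id = c("A1", "A1"), population = c(6000, 4001)))
classify_urban <- function(populations) {
  required <- c("nb_id", "area_id", "population")
  if (!all(required %in% names(populations))) {
    abort("populations needs columns nb_id, area_id, population.",
          class = "ambusy_schema_error")
  }
  if (any(!is.na(populations$area_id) & populations$area_id == "")) {
    abort("unknown (empty) area id.", class = "ambusy_classification_error")
  }
  area_pop <- populations |>
    dplyr::filter(!is.na(.data$area_id)) |>
    dplyr::group_by(.data$area_id) |>
    dplyr::summarise(total = sum(.data$population), .groups = "drop")
  populations |>
    dplyr::left_join(area_pop, by = "area_id") |>
    dplyr::mutate(urban = !is.na(.data$area_id) & !is.na(.data$total) &
                    .data$total > 10000) |>
    dplyr::select("nb_id", "urban")
}
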