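#' Build the spatial-temporal neighbor set for an incident
#'
#' Collects up to `max_n` nearest eligible incidents within `radius_km`
#' (great-circle, inclusive at the boundary) of the focal incident,
#' excluding all incidents on the focal's calendar day (which also removes
#' the focal itself). Neighbors are sorted ascending by distance with ties
#' broken by earlier call time, then incident id.
#'
#' @param focal One-row incident tibble with coordinates.
#' @param all_incidents Eligible incident tibble with coordinates, call
#'   times and responding-unit ids.
#' @param radius_km Search radius in km (default 15).
#' @param max_n Maximum neighbors (default 5000).
#' @param .index Optional precomputed [neighbor_index()] for repeated
#'   queries over the same cohort.
#' @return An `ambusy_neighbor_set`: list with `focal_id`, `focal_time` and
#'   a `neighbors` tibble (`incident_id`, `distance_km`, `unit_id`,
#'   `call_time`). Zero neighbors gives an empty tibble.
#' @export
build_neighbor_set <- function(focal, all_incidents, radius_km = 15,
                               max_n = 5000, .index = NULL) {
  if (is.na(focal$lat) || is.na(focal$lon)) {
    abort("focal incident lacks coordinates.", class = "ambusy_precondition_error")
  }
  vec <- cohort_vectors(all_incidents)
  sel <- ns_query(vec, focal_lat = focal$lat, focal_lon = focal$lon,
                  focal_day = as.integer(date_of(focal$call_time)),
                  radius_km = radius_km, max_n = max_n, index = .index)
  neighbors <- tibble::new_tibble(list(
    incident_id = vec$id[sel$idx],
    distance_km = sel$dist,
    unit_id = vec$unit[sel$idx],
    call_time = all_incidents$call_time[sel$idx]
  ), nrow = length(sel$idx))
  structure(list(focal_id = focal$incident_id,
                 focal_time = focal$call_time,
                 neighbors = neighbors),
            class = "ambusy_neighbor_set")
}

# plain-vector view of an incident cohort for the hot query path
cohort_vectors <- function(incidents) {
  list(id = incidents$incident_id,
       lat = incidents$lat,
       lon = incidents$lon,
       day = as.integer(date_of(incidents$call_time)),
       t = as.numeric(incidents$call_time),
       unit = incidents$unit_id,
       hour = hour_of(incidents$call_time),
       dow = dow_of(incidents$call_time))
}

# neighbor query on cohort vectors: indices (sorted by distance, call
# time, id) and distances of eligible neighbors
ns_query <- function(vec, focal_lat, focal_lon, focal_day,
                     radius_km = 15, max_n = 5000, index = NULL) {
  cand <- if (!is.null(index)) {
    index_candidates(index, focal_lat, focal_lon)
  } else {
    seq_along(vec$id)
  }
  cand <- cand[!is.na(vec$lat[cand]) & !is.na(vec$lon[cand]) &
                 vec$day[cand] != focal_day]
  if (length(cand) == 0) {
    return(list(idx = integer(0), dist = numeric(0)))
  }
  d <- haversine_km(vec$lat[cand], vec$lon[cand], focal_lat, focal_lon)
  keep <- d <= radius_km + 1e-9
  cand <- cand[keep]
  d <- d[keep]
  o <- order(d, vec$t[cand], vec$id[cand])
  o <- o[seq_len(min(length(o), max_n))]
  list(idx = cand[o], dist = d[o])
}

#' Spatial grid index for repeated neighbor queries
#'
#' Bins incidents into square cells of slightly more than `radius_km` on an
#' equirectangular projection; a query then only examines the 3x3 block of
#' cells around the focal point. Exact haversine filtering happens in
#' [build_neighbor_set()]; the index is only a superset pre-filter.
#'
#' @param incidents Incident tibble with `lat`/`lon`.
#' @param radius_km Query radius the index must cover.
#' @return An opaque index object.
#' @export
neighbor_index <- function(incidents, radius_km = 15) {
  lat0 <- mean(incidents$lat, na.rm = TRUE)
  cell <- radius_km * 1.1
  x <- (incidents$lon - 0) * 111 * cos(lat0 * pi / 180)
  y <- incidents$lat * 111
  cx <- floor(x / cell)
  cy <- floor(y / cell)
  key <- paste(cx, cy)
  structure(list(lat0 = lat0, cell = cell,
                 buckets = split(seq_len(nrow(incidents)), key)),
            class = "ambusy_neighbor_index")
}

index_candidates <- function(index, lat, lon) {
  x <- lon * 111 * cos(index$lat0 * pi / 180)
  y <- lat * 111
  cx <- floor(x / index$cell)
  cy <- floor(y / index$cell)
  keys <- as.vector(outer(cx + (-1:1), cy + (-1:1), paste))
  unlist(index$buckets[keys], use.names = FALSE)
}

#' Select candidate units from a neighbor set
#'
#' Keeps the up-to-`max_units` unit ids with the highest responder
#' frequency among the neighbors (ties broken by unit id); neighbors served
#' by other units are dropped from the training rows. The reference unit
#' for the multinomial model is the most frequent one.
#'
#' @param neighbors An `ambusy_neighbor_set`.
#' @param max_units Maximum number of candidate units (default 5).
#' @return List with `units` (ordered by descending frequency), `reference`,
#'   `counts`, and `dropped_fraction` (share of neighbor rows served by
#'   non-selected units).
#' @export
select_candidate_units <- function(neighbors, max_units = 5) {
  stopifnot(inherits(neighbors, "ambusy_neighbor_set"))
  tab <- table(neighbors$neighbors$unit_id)
  if (length(tab) == 0) {
    abort("neighbor set is empty; cannot select candidate units.",
          class = "ambusy_precondition_error")
  }
  o <- order(-as.integer(tab), names(tab))
  keep <- o[seq_len(min(max_units, length(o)))]
  units <- names(tab)[keep]
  list(units = units,
       reference = units[1],
       counts = as.integer(tab)[keep],
       dropped_fraction = 1 - sum(as.integer(tab)[keep]) / sum(tab))
}

#' Hour-of-day and day-of-week context of a call time
#'
#' @param time POSIXct call time.
#' @return List of class `ambusy_context` with `hour` (0-23) and `dow`
#'   (ISO 1-7).
#' @export
incident_context <- function(time) {
  structure(list(hour = hour_of(time), dow = dow_of(time)),
            class = "ambusy_context")
}
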