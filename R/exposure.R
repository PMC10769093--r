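#' Busy status of a unit at a point in time
#'
#' A unit is busy at a call time if some mission of that unit satisfies
#' `start <= call < end` (half-open at minute resolution). The mission
#' linked to the focal incident itself is excluded — otherwise every served
#' incident would count its own response as a busy signal. All missions
#' (primary and secondary, every urgency) count towards busy status.
#'
#' @param unit_id Character vector of unit ids (recycled against
#'   `call_time`).
#' @param call_time POSIXct call times.
#' @param missions Mission tibble with `unit_id`, `start_time`, `end_time`
#'   and optionally `incident_id`.
#' @param focal_incident_id Optional character vector of focal incident ids;
#'   a mission whose `incident_id` matches is ignored for that query.
#' @return Logical vector, `TRUE` where the unit is busy. Overlapping
#'   missions for a unit trigger a warning and are treated as busy.
#' @export
#' @examples
#' m <- tibble::tibble(unit_id = "U1",
#'   start_time = as.POSIXct("2020-01-01 10:00", tz = "UTC"),
#'   end_time = as.POSIXct("2020-01-01 11:00", tz = "UTC"),
#'   incident_id = NA_character_)
#' busy_status("U1", as.POSIXct("2020-01-01 10:30", tz = "UTC"), m)
busy_status <- function(unit_id, call_time, missions,
                        focal_incident_id = NULL) {
  n <- max(length(unit_id), length(call_time))
  unit_id <- rep_len(unit_id, n)
  call_time <- rep_len(call_time, n)
  if (!is.null(focal_incident_id)) {
    focal_incident_id <- rep_len(focal_incident_id, n)
  }
  if (!"incident_id" %in% names(missions)) {
    missions$incident_id <- NA_character_
  }
  tq <- as.numeric(call_time)
  out <- logical(n)
  for (u in unique(unit_id)) {
    rows <- which(unit_id == u)
    mu <- missions[missions$unit_id == u, , drop = FALSE]
    if (nrow(mu) == 0) next
    o <- order(as.numeric(mu$start_time))
    s <- as.numeric(mu$start_time)[o]
    e <- as.numeric(mu$end_time)[o]
    ids <- mu$incident_id[o]
    overlapping <- nrow(mu) > 1 && any(s[-1] < e[-length(e)])
    if (overlapping) {
      warn(sprintf("unit %s has overlapping missions; treating overlaps as busy.", u))
      for (r in rows) {
        hit <- s <= tq[r] & tq[r] < e
        if (!is.null(focal_incident_id)) {
          hit <- hit & (is.na(ids) | ids != focal_incident_id[r])
        }
        out[r] <- any(hit)
      }
    } else {
      k <- findInterval(tq[rows], s)
      hit <- k >= 1
      kk <- pmax(k, 1L)
      hit <- hit & tq[rows] < e[kk]
      if (!is.null(focal_incident_id)) {
        hit <- hit & (is.na(ids[kk]) | ids[kk] != focal_incident_id[rows])
      }
      out[rows] <- hit
    }
  }
  out
}

#' Busy-ambulance probability for one incident
#'
#' The exposure statistic: the sum of the candidate-response probabilities
#' of the units that were occupied at the incident time,
#' `sum_i P(A_i | t, d) * 1[unit i busy]`. With probabilities 0.6, 0.35 and
#' 0.05 for units A, B, C and A and C busy, the busy probability is
#' 0.6 + 0.05 = 0.65. The value is a plain dot product — never
#' re-normalized — so it lies in \[0, 1\] whenever the probabilities do.
#'
#' @param probs Named numeric vector of candidate probabilities (one per
#'   candidate unit; should sum to 1).
#' @param busy Named logical vector of busy indicators over the same units.
#' @return A single probability.
#' @export
#' @examples
#' busy_probability(c(A = 0.6, B = 0.35, C = 0.05),
#'                  c(A = TRUE, B = FALSE, C = TRUE))  # 0.65
busy_probability <- function(probs, busy) {
  if (length(probs) != length(busy)) {
    abort("probs and busy must cover the same candidate units.",
          class = "ambusy_contract_error")
  }
  if (!is.null(names(probs)) && !is.null(names(busy))) {
    if (!setequal(names(probs), names(busy))) {
      abort("probs and busy have different unit sets.",
            class = "ambusy_contract_error")
    }
    busy <- busy[names(probs)]
  }
  sum(probs * as.numeric(busy))
}

#' Number of candidate ambulances
#'
#' Counts the units whose predicted response probability is strictly above
#' the threshold (default 10%). For probabilities 0.6, 0.35, 0.05 this is 2.
#'
#' @param probs Numeric vector of candidate probabilities.
#' @param threshold Strict lower bound (default 0.10).
#' @return Integer count.
#' @export
#' @examples
#' count_candidates(c(0.6, 0.35, 0.05))  # 2
count_candidates <- function(probs, threshold = 0.10) {
  sum(probs > threshold)
}

#' Per-incident busy exposure over a cohort
#'
#' For each eligible incident this builds the spatial-temporal neighbor set
#' ([build_neighbor_set()]), selects up to `max_units` candidate units,
#' fits the localized multinomial model ([fit_local_multinomial()]),
#' predicts candidate probabilities at the incident's hour and weekday,
#' determines which candidates were busy, and computes the busy-ambulance
#' probability and candidate count.
#'
#' Incidents with fewer than `min_neighbors` neighbors, or whose model
#' fails to converge, are retained in the output with `status` recording
#' the reason and `busy_probability` set to `NA`.
#'
#' @param incidents Eligible incident tibble (filtered; coordinates
#'   present).
#' @param missions Mission tibble (all missions, both kinds).
#' @param radius_km,max_neighbors Neighbor-set parameters (defaults 15 km,
#'   5000).
#' @param max_units Maximum candidate units per incident (default 5).
#' @param min_neighbors Minimum neighbor count to attempt a model fit
#'   (default 50).
#' @param threshold Candidate-count probability threshold (default 0.10).
#' @param ridge Ridge penalty for the multinomial fit (default 1e-4).
#' @return A tibble with one row per incident: `incident_id`, `n_neighbors`,
#'   `n_units`, list-columns `units`, `probs`, `busy`, and scalars
#'   `busy_probability`, `n_candidates`, `status` (`"ok"`,
#'   `"too_few_neighbors"` or `"not_converged"`).
#' @export
estimate_busy_exposure <- function(incidents, missions,
                                   radius_km = 15, max_neighbors = 5000,
                                   max_units = 5, min_neighbors = 50,
                                   threshold = 0.10, ridge = 1e-4) {
  n <- nrow(incidents)
  idx <- neighbor_index(incidents, radius_km)
  vec <- cohort_vectors(incidents)
  units_l <- vector("list", n)
  probs_l <- vector("list", n)
  busy_l <- vector("list", n)
  n_neigh <- integer(n)
  n_units <- integer(n)
  busy_p <- rep(NA_real_, n)
  n_cand <- rep(NA_integer_, n)
  status <- character(n)

  mission_idx <- split_missions(missions)
  # identical count tables yield identical fits; memoize on the table
  fit_cache <- new.env(parent = emptyenv())

  for (i in seq_len(n)) {
    sel_idx <- ns_query(vec, focal_lat = vec$lat[i],
                        focal_lon = vec$lon[i], focal_day = vec$day[i],
                        radius_km = radius_km, max_n = max_neighbors,
                        index = idx)$idx
    n_neigh[i] <- length(sel_idx)
    if (n_neigh[i] < min_neighbors) {
      status[i] <- "too_few_neighbors"
      units_l[[i]] <- character(0)
      probs_l[[i]] <- numeric(0)
      busy_l[[i]] <- logical(0)
      next
    }
    resp <- vec$unit[sel_idx]
    cnt <- table(resp)
    o <- order(-as.integer(cnt), names(cnt))
    keep <- o[seq_len(min(max_units, length(o)))]
    units <- names(cnt)[keep]

    if (length(units) == 1) {
      pr <- setNames(1, units)
    } else {
      train <- sel_idx[resp %in% units]
      tab <- context_count_table(vec$hour[train], vec$dow[train],
                                 vec$unit[train], units)
      key <- paste(c(length(tab$hour_levels), tab$hour_levels,
                     tab$dow_levels, units, tab$ctx_hour, tab$ctx_dow,
                     as.integer(tab$N)), collapse = ",")
      fit <- fit_cache[[key]]
      if (is.null(fit)) {
        base <- list(units = units, reference = units[1],
                     n_neighbors = n_neigh[i], n_train = length(train))
        fit <- fit_from_table(tab, units, base, ridge = ridge)
        fit_cache[[key]] <- fit
      }
      if (!fit$converged) {
        status[i] <- "not_converged"
        units_l[[i]] <- units
        probs_l[[i]] <- numeric(0)
        busy_l[[i]] <- logical(0)
        next
      }
      ctx <- structure(list(hour = vec$hour[i], dow = vec$dow[i]),
                       class = "ambusy_context")
      pr <- predict_candidate_probs(fit, ctx)
    }
    flags <- busy_status_indexed(names(pr), incidents$call_time[i],
                                 mission_idx, vec$id[i])
    names(flags) <- names(pr)
    units_l[[i]] <- names(pr)
    probs_l[[i]] <- pr
    busy_l[[i]] <- flags
    n_units[i] <- length(pr)
    busy_p[i] <- busy_probability(pr, flags)
    n_cand[i] <- count_candidates(pr, threshold)
    status[i] <- "ok"
  }

  tibble(
    incident_id = incidents$incident_id,
    n_neighbors = n_neigh,
    n_units = n_units,
    units = units_l, probs = probs_l, busy = busy_l,
    busy_probability = busy_p,
    n_candidates = n_cand,
    status = status
  )
}

# Pre-indexed mission lookup: per unit, sorted numeric start/end and
# incident ids. Used by the exposure loop to avoid re-subsetting.
split_missions <- function(missions) {
  if (!"incident_id" %in% names(missions)) {
    missions$incident_id <- NA_character_
  }
  out <- list()
  for (u in unique(missions$unit_id)) {
    mu <- missions[missions$unit_id == u, , drop = FALSE]
    o <- order(as.numeric(mu$start_time))
    out[[u]] <- list(s = as.numeric(mu$start_time)[o],
                     e = as.numeric(mu$end_time)[o],
                     id = mu$incident_id[o])
  }
  out
}

busy_status_indexed <- function(unit_ids, call_time, mission_idx, focal_id) {
  tq <- as.numeric(call_time)
  vapply(unit_ids, function(u) {
    mu <- mission_idx[[u]]
    if (is.null(mu)) return(FALSE)
    k <- findInterval(tq, mu$s)
    if (k < 1) return(FALSE)
    # scan back over missions starting before tq (overlap-safe)
    while (k >= 1) {
      if (tq < mu$e[k] && (is.na(mu$id[k]) || mu$id[k] != focal_id)) {
        return(TRUE)
      }
      # earlier missions can still cover tq only if intervals overlap;
      # typical logs are non-overlapping, so one extra step suffices
      if (k > 1 && mu$e[k - 1] <= mu$s[k]) break
      k <- k - 1
    }
    FALSE
  }, logical(1))
}
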