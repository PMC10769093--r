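#' Simulation configuration
#'
#' Bundles every knob of the synthetic ambulance-service simulator. Defaults
#' describe a mixed urban-rural regional service: ambulances drive at 80
#' km/h after a 2-minute mobilization, a primary mission occupies its unit
#' for the drive plus roughly an hour of on-scene, transport and return
#' time, and each unit additionally runs about 1.5 secondary (inter-facility
#' transfer) missions per day. The true causal delay when the overall
#' nearest (preferred) unit is occupied at call time is `delay_effect_min`
#' minutes; this is the ground-truth quantity the estimation stage is meant
#' to recover.
#'
#' @param horizon_days Length of the simulated period in days (>= 1).
#' @param seed Integer master seed; fans out into independent substreams for
#'   arrivals, timing, secondary missions, marks and defects.
#' @param start_date First day of the horizon (`Date` or string).
#' @param speed_kmh Ambulance travel speed over haversine distance.
#' @param mobilization_min Minutes from dispatch to wheels rolling.
#' @param delay_effect_min True extra response minutes incurred when the
#'   preferred unit is busy at call time (>= 0); draws are truncated normal
#'   with coefficient of variation `delay_cv`.
#' @param delay_cv Relative spread of the injected delay draw.
#' @param response_noise_mean,response_noise_sd Gamma-distributed extra
#'   response minutes (traffic, chute time) independent of busy status.
#' @param occupancy_extra_meanlog,occupancy_extra_sdlog Log-normal minutes a
#'   primary mission occupies its unit beyond the initial drive (on scene +
#'   transport + return).
#' @param secondary_rate Secondary missions per unit per day.
#' @param secondary_dur_meanlog,secondary_dur_sdlog Log-normal secondary
#'   mission duration (minutes).
#' @param missing_coord_rate,timestamp_error_rate Fractions of incident rows
#'   given data defects by [inject_defects()].
#' @param acute_fraction Fraction of incidents triaged acute; the remainder
#'   splits evenly between urgent and ordinary.
#' @param hour_mult,dow_mult Relative incident-intensity multipliers by hour
#'   of day (24) and ISO day of week (7); scaled internally to mean 1. Pass
#'   flat vectors to remove diurnal/weekly structure.
#'
#' @return A list of class `ambusy_sim_config`.
#' @export
sim_config <- function(horizon_days = 365,
                       seed = 1L,
                       start_date = "2019-01-01",
                       speed_kmh = 80,
                       mobilization_min = 2,
                       delay_effect_min = 6,
                       delay_cv = 0.25,
                       response_noise_mean = 3,
                       response_noise_sd = 2,
                       occupancy_extra_meanlog = log(55),
                       occupancy_extra_sdlog = 0.35,
                       secondary_rate = 1.5,
                       secondary_dur_meanlog = log(45),
                       secondary_dur_sdlog = 0.4,
                       missing_coord_rate = 0,
                       timestamp_error_rate = 0,
                       acute_fraction = 0.75,
                       hour_mult = NULL,
                       dow_mult = NULL) {
  if (horizon_days < 1) {
    abort("horizon_days must be at least 1.", class = "ambusy_config_error")
  }
  if (delay_effect_min < 0 || secondary_rate < 0 ||
      missing_coord_rate < 0 || missing_coord_rate > 1 ||
      timestamp_error_rate < 0 || timestamp_error_rate > 1) {
    abort("rates must be non-negative (defect rates in [0, 1]) and the delay effect >= 0.",
          class = "ambusy_config_error")
  }
  if (is.null(hour_mult)) {
    # quiet nights, midday/afternoon peak
    h <- c(rep(0.5, 6), 0.7, 0.9, 1.1, 1.2, 1.3, 1.35, 1.35, 1.4, 1.4,
           1.3, 1.25, 1.2, 1.15, 1.1, 1.0, 0.9, 0.8, 0.6)
    hour_mult <- h[1:24]
  }
  if (is.null(dow_mult)) dow_mult <- c(1, 0.95, 0.95, 1, 1.05, 1.1, 1.05)
  stopifnot(length(hour_mult) == 24, length(dow_mult) == 7,
            all(hour_mult > 0), all(dow_mult > 0))
  structure(list(
    horizon_days = as.integer(horizon_days), seed = as.integer(seed),
    start_date = as.Date(start_date),
    speed_kmh = speed_kmh, mobilization_min = mobilization_min,
    delay_effect_min = delay_effect_min, delay_cv = delay_cv,
    response_noise_mean = response_noise_mean,
    response_noise_sd = response_noise_sd,
    occupancy_extra_meanlog = occupancy_extra_meanlog,
    occupancy_extra_sdlog = occupancy_extra_sdlog,
    secondary_rate = secondary_rate,
    secondary_dur_meanlog = secondary_dur_meanlog,
    secondary_dur_sdlog = secondary_dur_sdlog,
    missing_coord_rate = missing_coord_rate,
    timestamp_error_rate = timestamp_error_rate,
    acute_fraction = acute_fraction,
    hour_mult = hour_mult / mean(hour_mult),
    dow_mult = dow_mult / mean(dow_mult)
  ), class = "ambusy_sim_config")
}

incident_types <- c("acute illness", "traffic accident", "other accident",
                    "psychiatry/intoxication", "fire",
                    "transport to hospital", "other")
urgency_levels <- c("acute", "urgent", "ordinary")

# haversine km between (lat, lon) vectors; geosphere wants (lon, lat)
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

# first time in the horizon (hour grid) at which no unit is on shift, or NULL
first_uncovered_time <- function(region, config) {
  t0 <- as.POSIXct(paste(config$start_date, "00:00"), tz = "UTC")
  grid <- t0 + 3600 * seq_len(min(config$horizon_days, 8L) * 24L) - 3600
  cover <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(region$units))) {
    cover <- cover | unit_on_shift(region$units[i, ], grid)
  }
  if (all(cover)) NULL else grid[which(!cover)[1]]
}

#' Simulate ambulance operations
#'
#' Runs a discrete-event simulation of the region over the configured
#' horizon. Incidents arrive by an inhomogeneous Poisson process per
#' neighbourhood (hour-of-day and day-of-week multipliers); each is served
#' by the nearest on-shift unit that is free at call time, or by the first
#' unit to free up when none is. When the overall-nearest (preferred) unit
#' is occupied at call time, the response time gains extra minutes drawn
#' around the configured true delay effect. Every response creates a
#' primary mission occupying the responding unit (drive + on-scene +
#' transport + return); secondary missions occupy units independently of
#' incident demand. All emitted timestamps are floored to whole minutes.
#'
#' @param region An [generate_region()] layout.
#' @param config An [sim_config()].
#'
#' @return A list of class `ambusy_sim` with tibbles:
#' \describe{
#'   \item{incidents}{`incident_id`, `call_time`, `lat`, `lon`, `urgency`,
#'     `incident_type`, `nb_id`, `urban`, `unit_id` (responder),
#'     `arrival_time`, `mission_kind`.}
#'   \item{missions}{`mission_id`, `unit_id`, `start_time`, `end_time`,
#'     `kind`, `incident_id` (NA for secondary missions).}
#'   \item{ground_truth}{`incident_id`, `preferred_unit`, `truly_busy`
#'     (recomputed from the emitted minute-resolution mission log),
#'     `true_travel_min` (uncontended mobilization + drive).}
#' }
#' @export
simulate_operations <- function(region, config = sim_config()) {
  stopifnot(inherits(region, "ambusy_region"),
            inherits(config, "ambusy_sim_config"))
  uncov <- first_uncovered_time(region, config)
  if (!is.null(uncov)) {
    abort(sprintf("no unit on shift at %s; every hour needs coverage.",
                  format_minute(uncov)),
          class = "ambusy_sim_error")
  }

  t0 <- as.numeric(as.POSIXct(paste(config$start_date, "00:00"), tz = "UTC"))
  n_hours <- config$horizon_days * 24L
  nb <- region$neighbourhoods
  units <- region$units
  st <- region$stations
  unit_lat <- st$lat[match(units$station_id, st$station_id)]
  unit_lon <- st$lon[match(units$station_id, st$station_id)]
  n_units <- nrow(units)

  ## --- arrivals (per neighbourhood x hour Poisson) --------------------
  hour_seq <- seq_len(n_hours) - 1L
  hour_of_day <- hour_seq %% 24L
  day_idx <- hour_seq %/% 24L
  dow <- (as.integer(format(config$start_date, "%w")) + day_idx) %% 7L
  dow <- ifelse(dow == 0L, 7L, dow)
  mult <- config$hour_mult[hour_of_day + 1L] * config$dow_mult[dow]

  arr <- with_seed(derive_seed(config$seed, "arrivals"), {
    counts <- rpois(n_hours * nrow(nb),
                    lambda = rep(nb$intensity, each = n_hours) * rep(mult, nrow(nb)))
    nb_idx <- rep(rep(seq_len(nrow(nb)), each = n_hours), counts)
    hr_idx <- rep(rep(hour_seq, nrow(nb)), counts)
    times <- t0 + hr_idx * 3600 + runif(length(nb_idx)) * 3600
    ord <- order(times)
    list(nb_idx = nb_idx[ord], times = times[ord])
  })
  n_inc <- length(arr$times)
  if (n_inc == 0) {
    abort("simulation produced no incidents; increase intensities or horizon.",
          class = "ambusy_sim_error")
  }

  marks <- with_seed(derive_seed(config$seed, "marks"), {
    km_deg <- 1 / 111
    list(
      lat = nb$lat[arr$nb_idx] + rnorm(n_inc, 0, 1.0 * km_deg),
      lon = nb$lon[arr$nb_idx] + rnorm(n_inc, 0, 1.0 * km_deg /
                                         cos(mean(nb$lat) * pi / 180)),
      urgency = sample(urgency_levels, n_inc, replace = TRUE,
                       prob = c(config$acute_fraction,
                                (1 - config$acute_fraction) / 2,
                                (1 - config$acute_fraction) / 2)),
      type = sample(incident_types, n_inc, replace = TRUE,
                    prob = c(0.35, 0.12, 0.12, 0.12, 0.05, 0.14, 0.10))
    )
  })

  draws <- with_seed(derive_seed(config$seed, "timing"), {
    shp <- (config$response_noise_mean / config$response_noise_sd)^2
    rte <- config$response_noise_mean / config$response_noise_sd^2
    list(
      noise = stats::rgamma(n_inc, shape = shp, rate = rte),
      delay = if (config$delay_effect_min > 0) {
        pmax(0, rnorm(n_inc, config$delay_effect_min,
                      config$delay_cv * config$delay_effect_min))
      } else rep(0, n_inc),
      occ_extra = rlnorm(n_inc, config$occupancy_extra_meanlog,
                         config$occupancy_extra_sdlog)
    )
  })

  ## --- travel times and schedules, vectorised ------------------------
  # minutes from each unit's station to each incident
  travel <- matrix(0, n_inc, n_units)
  for (u in seq_len(n_units)) {
    travel[, u] <- config$mobilization_min +
      haversine_km(marks$lat, marks$lon, unit_lat[u], unit_lon[u]) /
      config$speed_kmh * 60
  }
  call_pos <- as.POSIXct(arr$times, origin = "1970-01-01", tz = "UTC")
  on_shift <- matrix(FALSE, n_inc, n_units)
  for (u in seq_len(n_units)) {
    on_shift[, u] <- unit_on_shift(units[u, ], call_pos)
  }
  if (any(rowSums(on_shift) == 0)) {
    bad <- which(rowSums(on_shift) == 0)[1]
    abort(sprintf("no unit on shift at %s.", format_minute(call_pos[bad])),
          class = "ambusy_sim_error")
  }
  trav_shift <- travel
  trav_shift[!on_shift] <- Inf
  preferred <- max.col(-trav_shift, ties.method = "first")

  ## --- secondary mission requests -------------------------------------
  sec <- with_seed(derive_seed(config$seed, "secondary"), {
    if (config$secondary_rate > 0) {
      cnt <- rpois(n_units * config$horizon_days, config$secondary_rate)
      u_idx <- rep(rep(seq_len(n_units), config$horizon_days), cnt)
      d_idx <- rep(rep(seq_len(config$horizon_days) - 1L, each = n_units), cnt)
      times <- t0 + d_idx * 86400 + runif(length(u_idx)) * 86400
      dur <- rlnorm(length(u_idx), config$secondary_dur_meanlog,
                    config$secondary_dur_sdlog)
      ord <- order(times)
      list(u = u_idx[ord], t = times[ord], dur = dur[ord])
    } else list(u = integer(0), t = numeric(0), dur = numeric(0))
  })

  ## --- event loop ------------------------------------------------------
  ev_t <- c(arr$times, sec$t)
  ev_is_inc <- c(rep(TRUE, n_inc), rep(FALSE, length(sec$t)))
  ev_idx <- c(seq_len(n_inc), seq_along(sec$t))
  ord <- order(ev_t)
  busy_until <- rep(-Inf, n_units)

  responder <- integer(n_inc)
  busy_at_call <- logical(n_inc)
  resp_min <- numeric(n_inc)
  m_unit <- integer(n_inc + length(sec$t))
  m_start <- numeric(n_inc + length(sec$t))
  m_end <- numeric(n_inc + length(sec$t))
  m_kind <- character(n_inc + length(sec$t))
  m_inc <- rep(NA_integer_, n_inc + length(sec$t))
  n_mis <- 0L

  for (e in ord) {
    t <- ev_t[e]
    if (ev_is_inc[e]) {
      i <- ev_idx[e]
      p <- preferred[i]
      busy_at_call[i] <- busy_until[p] > t
      free <- on_shift[i, ] & busy_until <= t
      if (any(free)) {
        tv <- trav_shift[i, ]
        tv[!free] <- Inf
        r <- which.min(tv)
        start <- t
      } else {
        cand <- which(on_shift[i, ])
        r <- cand[which.min(busy_until[cand])]
        start <- busy_until[r]
      }
      responder[i] <- r
      resp_min[i] <- travel[i, p] + draws$noise[i] +
        if (busy_at_call[i]) draws$delay[i] else 0
      occ <- travel[i, r] + draws$occ_extra[i]
      n_mis <- n_mis + 1L
      m_unit[n_mis] <- r
      m_start[n_mis] <- start
      m_end[n_mis] <- start + occ * 60
      m_kind[n_mis] <- "primary"
      m_inc[n_mis] <- i
      busy_until[r] <- start + occ * 60
    } else {
      j <- ev_idx[e]
      u <- sec$u[j]
      if (busy_until[u] <= t && unit_on_shift(units[u, ],
            as.POSIXct(t, origin = "1970-01-01", tz = "UTC"))) {
        n_mis <- n_mis + 1L
        m_unit[n_mis] <- u
        m_start[n_mis] <- t
        m_end[n_mis] <- t + sec$dur[j] * 60
        m_kind[n_mis] <- "secondary"
        busy_until[u] <- t + sec$dur[j] * 60
      }
    }
  }

  ## --- assemble minute-floored tables ---------------------------------
  inc_ids <- sprintf("I%06d", seq_len(n_inc))
  call_floor <- floor_minute(call_pos)
  arrival_floor <- floor_minute(call_pos + resp_min * 60)
  incidents <- tibble(
    incident_id = inc_ids,
    call_time = call_floor,
    lat = marks$lat, lon = marks$lon,
    urgency = marks$urgency,
    incident_type = marks$type,
    nb_id = nb$nb_id[arr$nb_idx],
    urban = nb$urban[arr$nb_idx],
    unit_id = units$unit_id[responder],
    arrival_time = arrival_floor,
    mission_kind = "primary"
  )
  keep <- seq_len(n_mis)
  missions <- tibble(
    mission_id = sprintf("M%06d", keep),
    unit_id = units$unit_id[m_unit[keep]],
    start_time = floor_minute(as.POSIXct(m_start[keep], origin = "1970-01-01",
                                         tz = "UTC")),
    end_time = floor_minute(as.POSIXct(m_end[keep], origin = "1970-01-01",
                                       tz = "UTC")),
    kind = m_kind[keep],
    incident_id = ifelse(is.na(m_inc[keep]), NA_character_,
                         inc_ids[m_inc[keep]])
  )
  # a minute-floored mission could collapse to zero length; keep end > start
  missions$end_time <- pmax(missions$end_time, missions$start_time + 60)

  # ground truth busy flag recomputed from the emitted (floored) log with
  # the same half-open, self-excluding rule the exposure stage uses
  truly_busy <- busy_status(units$unit_id[preferred], incidents$call_time,
                            missions, focal_incident_id = inc_ids)
  ground_truth <- tibble(
    incident_id = inc_ids,
    preferred_unit = units$unit_id[preferred],
    truly_busy = truly_busy,
    true_travel_min = travel[cbind(seq_len(n_inc), preferred)]
  )

  structure(list(incidents = incidents, missions = missions,
                 ground_truth = ground_truth, config = config),
            class = "ambusy_sim")
}

#' @export
print.ambusy_sim <- function(x, ...) {
  cat(sprintf(
    "<ambusy_sim> %d incidents, %d missions (%d secondary), busy-at-call %.1f%%\n",
    nrow(x$incidents), nrow(x$missions),
    sum(x$missions$kind == "secondary"),
    100 * mean(x$ground_truth$truly_busy)))
  invisible(x)
}

#' Inject data defects into an incident table
#'
#' Reproduces the data-quality problems of real dispatch logs: a fraction
#' of rows loses its coordinates and a (disjoint) fraction gets a perturbed
#' arrival timestamp yielding a negative or longer-than-six-hour response
#' time. Both kinds are exactly the eligibility defects the ingest filter
#' removes. Counts are deterministic: `round(rate * n)` rows per defect,
#' missing coordinates assigned first.
#'
#' @param incidents Incident tibble (as from [simulate_operations()]).
#' @param config An [sim_config()] carrying `missing_coord_rate` and
#'   `timestamp_error_rate`.
#' @param seed Integer seed for defect-row selection.
#'
#' @return The incident tibble with defects applied and a hidden audit
#'   column `.defect` in `{"none", "missing_coords", "timestamp"}`.
#' @export
inject_defects <- function(incidents, config, seed = config$seed) {
  stopifnot(config$missing_coord_rate >= 0, config$missing_coord_rate <= 1,
            config$timestamp_error_rate >= 0, config$timestamp_error_rate <= 1)
  n <- nrow(incidents)
  out <- incidents
  out$.defect <- rep("none", n)
  if (n == 0) return(out)
  with_seed(derive_seed(seed, "defects"), {
    n_miss <- round(config$missing_coord_rate * n)
    miss_rows <- if (n_miss > 0) sample.int(n, n_miss) else integer(0)
    remainder <- setdiff(seq_len(n), miss_rows)
    n_ts <- min(round(config$timestamp_error_rate * n), length(remainder))
    ts_rows <- if (n_ts > 0) sample(remainder, n_ts) else integer(0)

    out$lat[miss_rows] <- NA_real_
    out$lon[miss_rows] <- NA_real_
    out$.defect[miss_rows] <- "missing_coords"

    if (n_ts > 0) {
      neg <- runif(n_ts) < 0.5
      shift <- ifelse(neg, -round(runif(n_ts, 5, 120)),
                      round(runif(n_ts, 361, 900)))
      out$arrival_time[ts_rows] <- out$call_time[ts_rows] + shift * 60
      out$.defect[ts_rows] <- "timestamp"
    }
  })
  out
}

#' Write simulator output as delimited logs
#'
#' Emits `incidents.csv`, `missions.csv` and `ground_truth.csv` (headered,
#' comma-delimited, ISO-8601 minute timestamps, WGS84 decimal degrees) plus
#' a `config.yaml` sidecar echoing the full configuration and seed.
#'
#' @param sim An `ambusy_sim` result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_ems_logs <- function(sim, dir) {
  stopifnot(inherits(sim, "ambusy_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  inc <- sim$incidents
  inc$call_time <- format_minute(inc$call_time)
  inc$arrival_time <- format_minute(inc$arrival_time)
  inc$.defect <- NULL
  mis <- sim$missions
  mis$start_time <- format_minute(mis$start_time)
  mis$end_time <- format_minute(mis$end_time)
  paths <- c(incidents = file.path(dir, "incidents.csv"),
             missions = file.path(dir, "missions.csv"),
             ground_truth = file.path(dir, "ground_truth.csv"),
             config = file.path(dir, "config.yaml"))
  readr::write_csv(inc, paths["incidents"])
  readr::write_csv(mis, paths["missions"])
  readr::write_csv(sim$ground_truth, paths["ground_truth"])
  cfg <- unclass(sim$config)
  cfg$start_date <- as.character(cfg$start_date)
  yaml::write_yaml(cfg, paths["config"])
  invisible(paths)
}
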