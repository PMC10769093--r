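# Shared fixtures and independent oracles. Heavy simulated cohorts are
# cached per test run so several files can share them.

.ambusy_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (!exists(key, envir = .ambusy_cache)) {
    assign(key, compute(), envir = .ambusy_cache)
  }
  get(key, envir = .ambusy_cache)
}

# The reference validation cohort: 10 stations, ~20k incidents over 540
# days, injected busy delay of 6 minutes, full exposure pipeline and
# overall fixed-effects fit with a 200-replicate Bayesian bootstrap.
big_run <- function() {
  cache_get("big_run", function() {
    region <- generate_region(n_stations = 10, n_neighbourhoods = 40,
                              urban_fraction = 0.3, seed = 101)
    cfg <- sim_config(horizon_days = 540, seed = 202, delay_effect_min = 6)
    sim <- simulate_operations(region, cfg)
    filt <- filter_incidents(sim$incidents)
    expo <- estimate_busy_exposure(filt$eligible, sim$missions)
    rows <- analysis_rows(filt$eligible, expo)
    fit <- fit_fixed_effects(rows)
    bb <- bayesian_bootstrap(rows, function(d, w) {
      f <- fit_fixed_effects(d, weights = w)
      c(delay_per_10pp = delay_per_10pp(f$coefficient))
    }, B = 200, seed = 303)
    list(region = region, sim = sim, eligible = filt$eligible,
         tally = filt$tally, exposure = expo, rows = rows, fit = fit,
         bootstrap = bb)
  })
}

# hand-rolled region with a single 24/7 unit (conservation tests)
single_unit_region <- function() {
  structure(list(
    stations = tibble::tibble(station_id = "S01", lat = 63.4, lon = 10.4,
                              urban = FALSE),
    units = tibble::tibble(unit_id = "S01-U1", station_id = "S01",
                           shift_start = 0, shift_end = 24,
                           days = "1234567"),
    neighbourhoods = tibble::tibble(
      nb_id = c("N001", "N002"), lat = c(63.43, 63.37),
      lon = c(10.44, 10.36), urban = FALSE, intensity = 0.03)
  ), class = "ambusy_region")
}

# minimal incident row for ingest/filter fixtures
make_incident <- function(id, call = "2021-05-03T12:00",
                          arrival = "2021-05-03T12:12",
                          lat = 63.4, lon = 10.4, urgency = "acute",
                          type = "acute illness", nb = "N001",
                          urban = FALSE, unit = "S01-U1",
                          kind = "primary") {
  tibble::tibble(
    incident_id = id,
    call_time = as.POSIXct(call, format = "%Y-%m-%dT%H:%M", tz = "UTC"),
    lat = lat, lon = lon, urgency = urgency, incident_type = type,
    nb_id = nb, urban = urban, unit_id = unit,
    arrival_time = if (is.na(arrival)) as.POSIXct(NA) else
      as.POSIXct(arrival, format = "%Y-%m-%dT%H:%M", tz = "UTC"),
    mission_kind = kind
  )
}

# a neighbor set built directly from (hour, dow, unit) training rows,
# bypassing the spatial search
make_neighbor_set <- function(hours, dows, units,
                              base_date = as.Date("2021-03-01")) {
  n <- length(units)
  hours <- rep_len(hours, n)
  dows <- rep_len(dows, n)
  # base_date is a Monday; offset days to hit the requested weekday
  call_time <- as.POSIXct(base_date, tz = "UTC") +
    (dows - 1) * 86400 + hours * 3600
  structure(list(
    focal_id = "FOCAL", focal_time = call_time[1],
    neighbors = tibble::tibble(
      incident_id = sprintf("nb%04d", seq_len(n)),
      distance_km = seq_len(n) * 0.001,
      unit_id = units, call_time = call_time)
  ), class = "ambusy_neighbor_set")
}

# independent penalized multinomial log-likelihood (per-row, no
# aggregation; used to cross-check the package's Newton fit)
oracle_pll <- function(par, hours, dows, units, unit_levels,
                       hour_levels, dow_levels, ridge) {
  K <- length(unit_levels)
  p <- 1 + (length(hour_levels) - 1) + (length(dow_levels) - 1)
  B <- matrix(par, p, K - 1)
  ll <- 0
  for (r in seq_along(units)) {
    x <- c(1,
           as.numeric(hour_levels[-1] == hours[r]),
           as.numeric(dow_levels[-1] == dows[r]))
    eta <- c(0, drop(x %*% B))
    pr <- exp(eta - max(eta))
    pr <- pr / sum(pr)
    ll <- ll + log(pr[match(units[r], unit_levels)])
  }
  ll - ridge * sum(par^2)
}

# synthetic analysis rows with known delay structure (no simulator)
synthetic_rows <- function(n, n_groups = 6, delta = 0, seed = 1,
                           years = 2019) {
  withr::with_seed(seed, {
    g <- sample(n_groups, n, replace = TRUE)
    x <- runif(n)
    year <- sample(rep(years, length.out = max(2, length(years))), n,
                   replace = TRUE)
    tibble::tibble(
      incident_id = sprintf("R%05d", seq_len(n)),
      response_time = 10 + 2 * g + delta * x + rnorm(n, 0, 3),
      busy_probability = x,
      nb_year = paste0("G", g, ":", year),
      year = year,
      month = sample(1:12, n, replace = TRUE),
      dow = sample(1:7, n, replace = TRUE),
      hour = sample(0:23, n, replace = TRUE),
      urban = g <= n_groups / 2,
      n_candidates = sample(1:4, n, replace = TRUE),
      incident_type = sample(c("acute illness", "fire", "traffic accident"),
                             n, replace = TRUE)
    )
  })
}

# explicit dummy-variable OLS oracle for the within estimator
lm_dummy_coef <- function(rows, weights = NULL) {
  d <- data.frame(y = rows$response_time, x = rows$busy_probability,
                  g = factor(rows$nb_year), m = factor(rows$month),
                  dw = factor(rows$dow), h = factor(rows$hour))
  f <- stats::lm(y ~ x + g + m + dw + h, data = d, weights = weights)
  unname(stats::coef(f)[["x"]])
}
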