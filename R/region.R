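#' Generate a synthetic ambulance-service region
#'
#' Lays out ambulance stations, their units (with weekly operating
#' schedules), and neighbourhoods on a latitude/longitude plane. Urban
#' neighbourhoods are clustered around a subset of stations and carry higher
#' incident intensities and more units with longer operating hours; rural
#' neighbourhoods are dispersed, usually covered by a single around-the-clock
#' unit. The layout mimics a mixed urban-rural region where several
#' ambulances with different operating hours may serve the same area.
#'
#' @param n_stations Number of ambulance stations (>= 1).
#' @param n_neighbourhoods Number of neighbourhoods (>= `n_stations`).
#' @param urban_fraction Proportion of neighbourhoods classified urban, in
#'   \[0, 1\]. The urban count is `round(urban_fraction * n_neighbourhoods)`.
#' @param seed Integer seed; the layout is deterministic given the seed.
#'
#' @return An object of class `ambusy_region`: a list with tibbles
#'   `stations` (`station_id`, `lat`, `lon`, `urban`), `units` (`unit_id`,
#'   `station_id`, `shift_start`, `shift_end` in hours, `days` as an ISO
#'   weekday string, e.g. `"12345"` for weekdays), and `neighbourhoods`
#'   (`nb_id`, `lat`, `lon`, `urban`, `intensity` in expected incidents per
#'   hour).
#' @export
#' @examples
#' region <- generate_region(n_stations = 3, n_neighbourhoods = 12,
#'                           urban_fraction = 0.25, seed = 1)
#' region$neighbourhoods
generate_region <- function(n_stations, n_neighbourhoods,
                            urban_fraction = 0.3, seed = 1L) {
  if (!is.numeric(n_stations) || n_stations < 1 ||
      !is.numeric(n_neighbourhoods) || n_neighbourhoods < 1) {
    abort("n_stations and n_neighbourhoods must be positive counts.",
          class = "ambusy_config_error")
  }
  if (n_neighbourhoods < n_stations) {
    abort("n_neighbourhoods must be at least n_stations.",
          class = "ambusy_config_error")
  }
  if (urban_fraction < 0 || urban_fraction > 1) {
    abort("urban_fraction must lie in [0, 1].",
          class = "ambusy_config_error")
  }
  n_stations <- as.integer(n_stations)
  n_neighbourhoods <- as.integer(n_neighbourhoods)

  with_seed(derive_seed(seed, "region"), {
    centre <- c(lat = 63.4, lon = 10.4)
    n_urban_nb <- round(urban_fraction * n_neighbourhoods)
    n_urban_st <- if (n_urban_nb > 0) max(1L, round(urban_fraction * n_stations)) else 0L
    n_urban_st <- min(n_urban_st, n_stations)

    # ~1 deg lat = 111 km; lon shrunk by cos(lat). Stations: urban cluster
    # within ~8 km of centre, rural dispersed over a ~160 km box.
    km_lat <- 1 / 111
    km_lon <- 1 / (111 * cos(centre["lat"] * pi / 180))
    st_urban <- n_stations > 0 & seq_len(n_stations) <= n_urban_st
    st_lat <- ifelse(st_urban,
                     centre["lat"] + rnorm(n_stations, 0, 4 * km_lat),
                     centre["lat"] + runif(n_stations, -80, 80) * km_lat)
    st_lon <- ifelse(st_urban,
                     centre["lon"] + rnorm(n_stations, 0, 4 * km_lon),
                     centre["lon"] + runif(n_stations, -80, 80) * km_lon)
    stations <- tibble(
      station_id = sprintf("S%02d", seq_len(n_stations)),
      lat = as.numeric(st_lat), lon = as.numeric(st_lon),
      urban = st_urban
    )

    units <- purrr::map_dfr(seq_len(n_stations), function(i) {
      sid <- stations$station_id[i]
      if (stations$urban[i]) {
        n_extra <- sample(1:2, 1)
        out <- tibble(
          unit_id = sprintf("%s-U%d", sid, seq_len(1 + n_extra)),
          station_id = sid,
          shift_start = c(0, 8, 10)[seq_len(1 + n_extra)],
          shift_end = c(24, 20, 22)[seq_len(1 + n_extra)],
          days = c("1234567", "1234567", "12345")[seq_len(1 + n_extra)]
        )
      } else {
        extra <- runif(1) < 0.3
        out <- tibble(
          unit_id = sprintf("%s-U%d", sid, seq_len(1 + extra)),
          station_id = sid,
          shift_start = c(0, 8)[seq_len(1 + extra)],
          shift_end = c(24, 18)[seq_len(1 + extra)],
          days = c("1234567", "12345")[seq_len(1 + extra)]
        )
      }
      out
    })

    nb_urban <- seq_len(n_neighbourhoods) <= n_urban_nb
    # urban neighbourhoods scatter around urban stations; rural ones around
    # rural stations (or anywhere if the region has no rural station)
    host_for <- function(urban_flag) {
      pool <- which(stations$urban == urban_flag)
      if (length(pool) == 0) pool <- seq_len(n_stations)
      if (length(pool) == 1) pool else sample(pool, 1)
    }
    host <- vapply(nb_urban, host_for, integer(1))
    spread_km <- ifelse(nb_urban, 3, 18)
    nb_lat <- stations$lat[host] + rnorm(n_neighbourhoods, 0, spread_km * km_lat)
    nb_lon <- stations$lon[host] + rnorm(n_neighbourhoods, 0, spread_km * km_lon)
    intensity <- ifelse(nb_urban,
                        runif(n_neighbourhoods, 0.05, 0.10),
                        runif(n_neighbourhoods, 0.02, 0.05))
    neighbourhoods <- tibble(
      nb_id = sprintf("N%03d", seq_len(n_neighbourhoods)),
      lat = as.numeric(nb_lat), lon = as.numeric(nb_lon),
      urban = nb_urban,
      intensity = intensity
    )

    structure(
      list(stations = stations, units = units,
           neighbourhoods = neighbourhoods),
      class = "ambusy_region"
    )
  })
}

#' @export
print.ambusy_region <- function(x, ...) {
  cat(sprintf(
    "<ambusy_region> %d stations, %d units, %d neighbourhoods (%d urban)\n",
    nrow(x$stations), nrow(x$units), nrow(x$neighbourhoods),
    sum(x$neighbourhoods$urban)))
  invisible(x)
}

# TRUE if the unit is on shift at POSIXct time t (vectorised over t)
unit_on_shift <- function(unit_row, t) {
  h <- hour_of(t) + as.integer(format(t, "%M", tz = "UTC")) / 60
  d <- dow_of(t)
  in_days <- vapply(d, function(dd) grepl(as.character(dd), unit_row$days),
                    logical(1))
  in_days & h >= unit_row$shift_start & h < unit_row$shift_end
}
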