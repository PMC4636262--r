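#' Define a synthetic regional climate scenario
#'
#' Describes a gridded daily temperature generator emulating the structure
#' of blended gridded observations: a seasonal cosine cycle around a
#' regional annual mean, a linear latitudinal gradient, a constant diurnal
#' range splitting the daily mean into tmax/tmin, region-wide daily weather
#' noise, optional independent per-cell noise, and an optional step warming
#' between two climate periods.
#'
#' The daily mean temperature of a cell is
#' `annual_mean + lat_gradient * (lat - lat_ref) +
#'  seasonal_amplitude * cos(2 * pi * (doy - phase_day) / 365.25) +
#'  warming * [year >= change_year] + regional daily anomaly + cell noise`,
#' and `tmax/tmin = tmean +/- diurnal_range / 2`. The cosine period of
#' 365.25 days keeps the seasonal phase stable across years. The daily
#' anomaly is shared by all cells of the grid (weather systems are much
#' larger than a 0.25-degree cell); `cell_noise_sd` adds independent
#' sub-grid noise on top when positive.
#'
#' @param annual_mean Regional annual mean temperature, degrees C.
#' @param seasonal_amplitude Half peak-to-trough seasonal amplitude,
#'   degrees C.
#' @param phase_day Day-of-year of the seasonal temperature peak.
#' @param diurnal_range `tmax - tmin`, degrees C (constant).
#' @param lat_gradient Change of mean temperature per degree latitude,
#'   degrees C per degree (negative = colder northward).
#' @param daily_noise_sd SD of the region-wide daily temperature anomaly,
#'   degrees C.
#' @param cell_noise_sd SD of independent per-cell daily noise, degrees C.
#' @param warming Step warming, degrees C, added to all days of years at or
#'   after `change_year`.
#' @param change_year First year of the warmed period; defaults to the
#'   midpoint of `years` when `warming != 0`.
#' @param years Integer vector of calendar years to simulate.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class `climate_scenario`.
#' @export
climate_scenario <- function(annual_mean = 6.9, seasonal_amplitude = 11,
                             phase_day = 196, diurnal_range = 7,
                             lat_gradient = 0, daily_noise_sd = 2,
                             cell_noise_sd = 0, warming = 0,
                             change_year = NULL, years = 2003:2010,
                             seed = 1L) {
  if (diurnal_range < 0) ff_abort_config("`diurnal_range` must be >= 0.")
  if (daily_noise_sd < 0 || cell_noise_sd < 0) {
    ff_abort_config("Noise standard deviations must be >= 0.")
  }
  years <- sort(as.integer(years))
  if (length(years) == 0) ff_abort_config("`years` must be non-empty.")
  if (warming != 0 && is.null(change_year)) {
    change_year <- years[floor(length(years) / 2) + 1L]
  }
  structure(
    list(
      annual_mean = annual_mean, seasonal_amplitude = seasonal_amplitude,
      phase_day = phase_day, diurnal_range = diurnal_range,
      lat_gradient = lat_gradient, daily_noise_sd = daily_noise_sd,
      cell_noise_sd = cell_noise_sd, warming = warming,
      change_year = change_year, years = years, seed = as.integer(seed)
    ),
    class = "climate_scenario"
  )
}

#' @export
print.climate_scenario <- function(x, ...) {
  cat(sprintf(
    "<climate_scenario> mean %.1f C, amplitude %.1f C, %d year(s) %d-%d, seed %d\n",
    x$annual_mean, x$seasonal_amplitude, length(x$years),
    min(x$years), max(x$years), x$seed
  ))
  invisible(x)
}

#' Simulate gridded daily temperatures
#'
#' Draws a complete daily tmax/tmin series for every cell of the grid (or
#' a subset of cells) under a [climate_scenario()]. Identical scenario and
#' seed give bit-identical output.
#'
#' @param scenario A [climate_scenario()].
#' @param spec A [grid_spec()].
#' @param cells Optional tibble of `lon_index`, `lat_index` to simulate
#'   only a subset of cells (e.g. region members).
#' @return A temperature tibble (see [validate_temperature_grid()]) with the
#'   grid spec and scenario attached as attributes.
#' @export
simulate_temperature <- function(scenario, spec, cells = NULL) {
  stopifnot(inherits(scenario, "climate_scenario"), inherits(spec, "grid_spec"))
  centers <- cell_centers(spec)
  if (!is.null(cells)) {
    centers <- semi_join(centers, cells, by = c("lon_index", "lat_index"))
    if (nrow(centers) == 0) ff_abort_config("`cells` match no grid cells.")
  }
  centers <- arrange(centers, lon_index, lat_index)
  dates <- as.Date(unlist(purrr::map(
    scenario$years,
    ~ seq(as.Date(sprintf("%d-01-01", .x)), as.Date(sprintf("%d-12-31", .x)), 1)
  )), origin = "1970-01-01")
  parts <- date_parts(dates)
  n_days <- length(dates)
  n_cells <- nrow(centers)
  lat_ref <- mean(centers$lat)

  seasonal <- scenario$seasonal_amplitude *
    cos(2 * pi * (parts$doy - scenario$phase_day) / 365.25)
  warming <- if (!is.null(scenario$change_year)) {
    scenario$warming * (parts$year >= scenario$change_year)
  } else {
    0
  }
  withr::with_seed(scenario$seed, {
    day_anom <- rnorm(n_days, 0, scenario$daily_noise_sd)
    cell_noise <- if (scenario$cell_noise_sd > 0) {
      rnorm(n_days * n_cells, 0, scenario$cell_noise_sd)
    } else {
      0
    }
  })
  base <- scenario$annual_mean + seasonal + warming + day_anom
  tmean <- rep(base, times = n_cells) +
    scenario$lat_gradient * rep(centers$lat - lat_ref, each = n_days) +
    cell_noise
  out <- tibble(
    lon_index = rep(centers$lon_index, each = n_days),
    lat_index = rep(centers$lat_index, each = n_days),
    date = rep(dates, times = n_cells),
    tmax = tmean + scenario$diurnal_range / 2,
    tmin = tmean - scenario$diurnal_range / 2
  )
  attr(out, "grid_spec") <- spec
  attr(out, "scenario") <- scenario
  out
}

#' Define a synthetic observation process
#'
#' Describes how virtual citizen scientists turn the true first-flight date
#' of a grid cell into sighting records, under one of two mechanisms:
#'
#' * `"sva"`: each observer watches a fixed location with a persistent
#'   microclimate temperature offset `N(0, sva_offset_sd)`; the sighting is
#'   the first crossing of the degree-day constant on the offset series
#'   (all intra-cell scatter is real sub-grid temperature variability).
#' * `"oba"`: each observer reports the true cell first flight plus an
#'   independent non-negative delay (all intra-cell scatter is reporting
#'   bias). The default delay is geometric on 0, 1, 2, ... with the given
#'   mean, so it has mass at zero and the earliest-sighting estimator is
#'   consistent; `dist = "exponential"` selects a discretized exponential.
#'
#' @param mode `"sva"` or `"oba"`.
#' @param observers_per_cell Virtual observers (locations) per cell.
#' @param reporting_probability Probability that an observer's sighting is
#'   reported in a given year (in `(0, 1]`).
#' @param sva_offset_sd SD of the persistent per-location temperature
#'   offset, degrees C (SVA mode).
#' @param oba_delay List `list(dist = "geometric"|"exponential", mean =
#'   days)` (OBA mode).
#' @param seed Integer seed for the observation process.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(mode = c("sva", "oba"), observers_per_cell = 5,
                           reporting_probability = 1, sva_offset_sd = 0.5,
                           oba_delay = list(dist = "geometric", mean = 3),
                           seed = 1L) {
  mode <- match.arg(mode)
  if (reporting_probability <= 0 || reporting_probability > 1) {
    ff_abort_config("`reporting_probability` must be in (0, 1].")
  }
  if (observers_per_cell < 1) ff_abort_config("Need at least one observer per cell.")
  if (sva_offset_sd < 0) ff_abort_config("`sva_offset_sd` must be >= 0.")
  if (!oba_delay$dist %in% c("geometric", "exponential") ||
      oba_delay$mean < 0) {
    ff_abort_config("`oba_delay` must be geometric or exponential with mean >= 0.")
  }
  structure(
    list(
      mode = mode, observers_per_cell = as.integer(observers_per_cell),
      reporting_probability = reporting_probability,
      sva_offset_sd = sva_offset_sd, oba_delay = oba_delay,
      seed = as.integer(seed)
    ),
    class = "observer_model"
  )
}

## true first flight per cell-year: first crossing of the cell's own series
true_ff_table <- function(temps, dd_c, t0) {
  accumulate_dd(temps, t0, quiet = TRUE) |>
    group_by(lon_index, lat_index, year) |>
    summarise(
      true_ff = first_crossing(cum_dd, dd_c, day_of_year),
      .groups = "drop"
    )
}

draw_delays <- function(n, delay) {
  if (delay$mean == 0) return(rep(0L, n))
  if (delay$dist == "geometric") {
    rgeom(n, prob = 1 / (1 + delay$mean))
  } else {
    as.integer(floor(rexp(n, rate = 1 / delay$mean)))
  }
}

#' Simulate sighting records with known truth
#'
#' Generates citizen-science-style sighting records from a simulated
#' temperature grid, a true degree-day constant and base temperature, and
#' an [observer_model()]. Returns both the sightings (in the exact format
#' read by [read_sightings_csv()]) and a truth record holding the generator
#' configuration and the true first-flight day of every cell-year, so
#' calibration can be checked against known parameters.
#'
#' @param temps A simulated temperature tibble ([simulate_temperature()]).
#' @param dd_c True degree-day constant.
#' @param t0 True base temperature, degrees C.
#' @param observer An [observer_model()].
#' @param species Species label written into the records.
#' @return A list with `sightings` (tibble `species`, `date`, `lon`,
#'   `lat`) and `truth` (list: `dd_c`, `t0`, `ff` tibble of true per-cell
#'   first flights, `observer`, `scenario`).
#' @export
simulate_sightings <- function(temps, dd_c, t0, observer,
                               species = "Anthocharis cardamines") {
  stopifnot(inherits(observer, "observer_model"))
  spec <- attr(temps, "grid_spec")
  if (is.null(spec)) ff_abort_format("`temps` must carry a grid_spec attribute.")
  truth_ff <- true_ff_table(temps, dd_c, t0)
  parts <- date_parts(temps$date)
  temps2 <- as_tibble(temps) |>
    mutate(year = parts$year, day_of_year = parts$doy) |>
    arrange(lon_index, lat_index, year, day_of_year)
  cells <- distinct(temps2, lon_index, lat_index) |> arrange(lon_index, lat_index)
  m <- observer$observers_per_cell

  records <- withr::with_seed(observer$seed, {
    purrr::pmap(cells, function(lon_index, lat_index) {
      li <- lon_index; la <- lat_index
      cell <- temps2[temps2$lon_index == li & temps2$lat_index == la, ]
      lon0 <- spec$origin_lon + li * spec$cell_size
      lat0 <- spec$origin_lat + la * spec$cell_size
      loc_lon <- runif(m, lon0, lon0 + spec$cell_size)
      loc_lat <- runif(m, lat0, lat0 + spec$cell_size)
      years <- unique(cell$year)
      if (observer$mode == "sva") {
        offsets <- rnorm(m, 0, observer$sva_offset_sd)
        obs <- purrr::map(seq_len(m), function(j) {
          delta <- daily_delta_dd(cell$tmax + offsets[j],
                                  cell$tmin + offsets[j], t0)
          days <- vapply(years, function(y) {
            sel <- cell$year == y
            first_crossing(cumsum(delta[sel]), dd_c, cell$day_of_year[sel])
          }, integer(1))
          tibble(
            lon = loc_lon[j], lat = loc_lat[j], year = years, day = days
          )
        }) |>
          purrr::list_rbind()
      } else {
        tf <- truth_ff[truth_ff$lon_index == li & truth_ff$lat_index == la, ]
        obs <- tidyr::expand_grid(j = seq_len(m), year = tf$year) |>
          left_join(tf[, c("year", "true_ff")], by = "year")
        delays <- draw_delays(nrow(obs), observer$oba_delay)
        obs <- obs |>
          mutate(
            day = pmin(true_ff + delays, days_in_year(year)),
            lon = loc_lon[j], lat = loc_lat[j]
          ) |>
          select(lon, lat, year, day)
      }
      obs <- obs[!is.na(obs$day), ]
      if (observer$reporting_probability < 1) {
        obs <- obs[runif(nrow(obs)) < observer$reporting_probability, ]
      }
      obs
    }) |>
      purrr::list_rbind()
  })

  sightings <- records |>
    mutate(species = species, date = doy_to_date(year, day)) |>
    select(species, date, lon, lat) |>
    arrange(date, lon, lat)
  list(
    sightings = sightings,
    truth = list(
      dd_c = dd_c, t0 = t0, ff = truth_ff,
      observer = observer, scenario = attr(temps, "scenario")
    )
  )
}

#' Three-region synthetic transect emulating a steep climate gradient
#'
#' A packaged demonstration setup: three 3 x 3 cell regions along a
#' south-to-north transect with annual mean temperatures 8.2, 6.9 and
#' 3.6 degrees C (a warm maritime south with a damped seasonal cycle, and
#' an increasingly continental, colder north).
#'
#' @param years Calendar years to simulate.
#' @param seed Base seed; each region uses `seed`, `seed + 1`, `seed + 2`.
#' @param warming Optional step warming passed to each scenario.
#' @param change_year Optional first warmed year.
#' @return A named list with one element per region: `region` (name),
#'   `scenario`, `spec`, and `cells` (all 9 member cells).
#' @export
swedish_transect <- function(years = 2003:2010, seed = 1L, warming = 0,
                             change_year = NULL) {
  defs <- list(
    list(name = "Skane", mean = 8.2, amp = 9, origin = c(13.0, 55.5)),
    list(name = "Sormland-Stockholm", mean = 6.9, amp = 10.5,
         origin = c(16.5, 58.75)),
    list(name = "Medelpad-Angermanland", mean = 3.6, amp = 12,
         origin = c(16.75, 62.25))
  )
  out <- purrr::imap(defs, function(d, i) {
    spec <- grid_spec(d$origin[1], d$origin[2], n_lon = 3, n_lat = 3)
    list(
      region = d$name,
      scenario = climate_scenario(
        annual_mean = d$mean, seasonal_amplitude = d$amp,
        lat_gradient = -0.65, cell_noise_sd = 0.3,
        warming = warming, change_year = change_year,
        years = years, seed = seed + i - 1L
      ),
      spec = spec,
      cells = tidyr::expand_grid(lon_index = 0:2, lat_index = 0:2)
    )
  })
  names(out) <- purrr::map_chr(defs, "name")
  out
}
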