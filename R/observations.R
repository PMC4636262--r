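#' Keep the earliest sighting per location and year
#'
#' When the same location reports a species on several days within one
#' season, only the earliest entry per year is the first-flight (FF) record
#' for that location and year. Location identity is exact equality of the
#' (lon, lat) pair. The operation is idempotent.
#'
#' @param sightings A sightings tibble (`species`, `date`, `lon`, `lat`).
#' @return The sightings tibble with at most one row per
#'   (species, location, year), the earliest.
#' @export
dedupe_location_year <- function(sightings) {
  if (nrow(sightings) == 0) return(as_tibble(sightings))
  parts <- date_parts(sightings$date)
  as_tibble(sightings) |>
    mutate(year = parts$year) |>
    arrange(species, lon, lat, year, date) |>
    group_by(species, lon, lat, year) |>
    slice(1) |>
    ungroup() |>
    select(-year)
}

#' Build a first-flight dataset under an observation assumption
#'
#' Transforms deduplicated sighting records into per-assumption FF
#' observations attached to grid cells and regions:
#'
#' * `"sva"` (spatial variability assumption): every sighting is a correct,
#'   spatially variable FF date; all records within a cell are kept.
#' * `"oba"` (observation bias assumption): intra-cell scatter is reporting
#'   delay; only the earliest sighting per cell and year is kept (ties in
#'   the earliest date collapse to a single observation).
#'
#' Records that fall outside the grid extent or outside every region are
#' dropped, with dropped counts reported in a message.
#'
#' @param sightings Deduplicated sightings (see [dedupe_location_year()]).
#' @param regions Region membership tibble.
#' @param spec A [grid_spec()].
#' @param assumption `"sva"` or `"oba"`.
#' @param quiet Suppress the drop-count message.
#' @return An FF tibble: `assumption`, `region`, `lon_index`, `lat_index`,
#'   `year`, `day_of_year`, `lon`, `lat`.
#' @export
build_ff_dataset <- function(sightings, regions, spec,
                             assumption = c("sva", "oba"), quiet = FALSE) {
  assumption <- match.arg(assumption)
  regions <- validate_regions(regions, spec)
  x <- assign_cell(as_tibble(sightings), spec)
  n_raw <- nrow(x)
  x <- filter(x, !is.na(lon_index))
  n_grid <- nrow(x)
  x <- inner_join(x, regions, by = c("lon_index", "lat_index"),
                  relationship = "many-to-many")
  if (!quiet && n_raw > 0) {
    inform(sprintf(
      "build_ff_dataset: %d record(s) in, %d outside grid, %d outside regions, %d kept.",
      n_raw, n_raw - n_grid, n_grid - nrow(x), nrow(x)
    ))
  }
  if (nrow(x) == 0) {
    return(tibble(
      assumption = character(), region = character(),
      lon_index = integer(), lat_index = integer(), year = integer(),
      day_of_year = integer(), lon = double(), lat = double()
    ))
  }
  parts <- date_parts(x$date)
  x <- x |> mutate(year = parts$year, day_of_year = parts$doy)
  if (assumption == "oba") {
    x <- x |>
      arrange(region, lon_index, lat_index, year, day_of_year, lon, lat) |>
      group_by(region, lon_index, lat_index, year) |>
      slice(1) |>
      ungroup()
  }
  x |>
    transmute(
      assumption = assumption, region, lon_index, lat_index,
      year, day_of_year, lon, lat
    ) |>
    arrange(region, lon_index, lat_index, year, day_of_year)
}

#' Regional annual mean first-flight date
#'
#' Arithmetic mean day-of-year over all FF observations of each year present
#' in the dataset, per region and assumption. This is the observed series
#' the regional model is calibrated against.
#'
#' @param ff An FF tibble from [build_ff_dataset()].
#' @return A tibble `assumption`, `region`, `year`, `mean_ff`, `n_obs`.
#' @export
regional_annual_mean_ff <- function(ff) {
  if (nrow(ff) == 0) ff_abort_data("FF dataset is empty.")
  ff |>
    group_by(assumption, region, year) |>
    summarise(mean_ff = mean(day_of_year), n_obs = dplyr::n(), .groups = "drop")
}

#' Summary statistics of first-flight dates
#'
#' Three nested summaries per region and assumption, each a mean and a
#' standard deviation in days:
#'
#' * `spatiotemporal`: over all FF observations (full spatial and temporal
#'   variability of the point data);
#' * `spatial`: over the per-cell temporal means (variability among grid
#'   cells of their temporally averaged FF);
#' * `temporal`: over the per-year regional means (variability among years
#'   of the spatially averaged FF).
#'
#' Standard deviations use the sample (n - 1) definition; groups of size one
#' report SD 0.
#'
#' @param ff An FF tibble from [build_ff_dataset()].
#' @return A tibble `assumption`, `region`, `scope`, `mean_doy`, `sd_days`,
#'   `n`.
#' @export
ff_summary_stats <- function(ff) {
  if (nrow(ff) == 0) ff_abort_data("FF dataset is empty.")
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  st <- ff |>
    group_by(assumption, region) |>
    summarise(
      scope = "spatiotemporal", mean_doy = mean(day_of_year),
      sd_days = sd0(day_of_year), n = dplyr::n(), .groups = "drop"
    )
  sp <- ff |>
    group_by(assumption, region, lon_index, lat_index) |>
    summarise(cell_mean = mean(day_of_year), .groups = "drop") |>
    group_by(assumption, region) |>
    summarise(
      scope = "spatial", mean_doy = mean(cell_mean),
      sd_days = sd0(cell_mean), n = dplyr::n(), .groups = "drop"
    )
  tm <- ff |>
    group_by(assumption, region, year) |>
    summarise(mean_ff = mean(day_of_year), .groups = "drop") |>
    group_by(assumption, region) |>
    summarise(
      scope = "temporal", mean_doy = mean(mean_ff),
      sd_days = sd0(mean_ff), n = dplyr::n(), .groups = "drop"
    )
  bind_rows(st, sp, tm) |>
    mutate(scope = factor(scope, c("spatiotemporal", "spatial", "temporal"))) |>
    arrange(assumption, region, scope)
}

#' Read and write first-flight datasets
#'
#' CSV with columns `assumption`, `region`, `cell_lon_index`,
#' `cell_lat_index`, `year`, `day_of_year`, `lon`, `lat`.
#'
#' @param ff An FF tibble.
#' @param path File path.
#' @export
write_ff_dataset <- function(ff, path) {
  out <- ff |>
    rename(cell_lon_index = lon_index, cell_lat_index = lat_index)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_ff_dataset
#' @export
read_ff_dataset <- function(path) {
  if (!file.exists(path)) ff_abort_format(sprintf("No such file: %s", path))
  readr::read_csv(
    path,
    col_types = readr::cols(
      assumption = readr::col_character(),
      region = readr::col_character(),
      cell_lon_index = readr::col_integer(),
      cell_lat_index = readr::col_integer(),
      year = readr::col_integer(),
      day_of_year = readr::col_integer(),
      lon = readr::col_double(),
      lat = readr::col_double()
    ),
    progress = FALSE
  ) |>
    rename(lon_index = cell_lon_index, lat_index = cell_lat_index)
}
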