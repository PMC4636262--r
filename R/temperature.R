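#' Validate a gridded daily temperature table
#'
#' A temperature table is a long-format tibble with one row per cell and day:
#' columns `lon_index`, `lat_index` (0-based cell indices), `date` (Date),
#' `tmax`, `tmin` (degrees C). Missing values are represented as `NA`, never
#' silently zero-filled; cell-years containing missing days or values are
#' excluded later, at degree-day accumulation time.
#'
#' Checks performed: required columns, `tmax >= tmin` wherever both are
#' present, and within each cell a strictly increasing daily calendar with a
#' step of one day.
#'
#' @param temps The temperature table.
#' @param spec Optional [grid_spec()]; when given, cell indices are checked
#'   against the grid bounds and attached as the `grid_spec` attribute.
#' @return `temps`, invisibly validated (as a tibble).
#' @export
validate_temperature_grid <- function(temps, spec = NULL) {
  need <- c("lon_index", "lat_index", "date", "tmax", "tmin")
  miss <- setdiff(need, names(temps))
  if (length(miss) > 0) {
    ff_abort_format(sprintf(
      "Temperature table lacks column(s): %s.", paste(miss, collapse = ", ")
    ))
  }
  if (!inherits(temps$date, "Date")) {
    ff_abort_format("`date` must be a Date column.")
  }
  both <- !is.na(temps$tmax) & !is.na(temps$tmin)
  if (any(temps$tmax[both] < temps$tmin[both])) {
    ff_abort_data("Found rows with tmax < tmin.")
  }
  bad_cal <- temps |>
    group_by(lon_index, lat_index) |>
    summarise(
      ok = all(diff(sort(as.integer(date))) == 1L) && !anyDuplicated(date),
      .groups = "drop"
    ) |>
    filter(!ok)
  if (nrow(bad_cal) > 0) {
    ff_abort_format(sprintf(
      "%d cell(s) have a non-contiguous or duplicated daily calendar.",
      nrow(bad_cal)
    ))
  }
  out <- as_tibble(temps)
  if (!is.null(spec)) {
    if (any(temps$lon_index < 0 | temps$lon_index >= spec$n_lon |
            temps$lat_index < 0 | temps$lat_index >= spec$n_lat)) {
      ff_abort_format("Temperature cells fall outside the grid bounds.")
    }
    attr(out, "grid_spec") <- spec
  }
  out
}

#' Read and write gridded daily temperatures (long-format CSV)
#'
#' The interchange format is a comma-separated, UTF-8, dot-decimal CSV with
#' header `lon_index,lat_index,date,tmax,tmin`; dates are ISO 8601, values
#' degrees C, missing values empty. The grid geometry travels in a JSON
#' sidecar written by [write_grid_spec()].
#'
#' @param path File path.
#' @param temps A temperature table (see [validate_temperature_grid()]).
#' @param spec Optional [grid_spec()] attached to the result.
#' @return `read_temperature_csv()` returns a validated temperature tibble;
#'   the writers return `path` invisibly.
#' @export
read_temperature_csv <- function(path, spec = NULL) {
  if (!file.exists(path)) ff_abort_format(sprintf("No such file: %s", path))
  temps <- readr::read_csv(
    path,
    col_types = readr::cols(
      lon_index = readr::col_integer(),
      lat_index = readr::col_integer(),
      date = readr::col_date(format = "%Y-%m-%d"),
      tmax = readr::col_double(),
      tmin = readr::col_double()
    ),
    progress = FALSE
  )
  validate_temperature_grid(temps, spec)
}

#' @rdname read_temperature_csv
#' @export
write_temperature_csv <- function(temps, path) {
  validate_temperature_grid(temps)
  readr::write_csv(
    temps[, c("lon_index", "lat_index", "date", "tmax", "tmin")],
    path, progress = FALSE
  )
  invisible(path)
}

#' @rdname read_temperature_csv
#' @export
write_grid_spec <- function(spec, path) {
  stopifnot(inherits(spec, "grid_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_temperature_csv
#' @export
read_grid_spec <- function(path) {
  x <- jsonlite::fromJSON(path)
  grid_spec(x$origin_lon, x$origin_lat, x$n_lon, x$n_lat, x$cell_size)
}

#' Read sighting records from CSV
#'
#' Sightings are point observations of a species on a date: CSV columns
#' `species`, `date` (ISO 8601), `lon`, `lat` (decimal degrees). Rows whose
#' date does not parse as a valid ISO date raise an error naming the
#' offending file line(s).
#'
#' @param path File path.
#' @param species_filter Optional species name; only matching rows are kept.
#' @return A tibble of sighting records with `date` parsed as Date.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "species,date,lon,lat",
#'   "Anthocharis cardamines,2005-05-12,17.1,59.2"
#' ), f)
#' read_sightings_csv(f, "Anthocharis cardamines")
#' @export
read_sightings_csv <- function(path, species_filter = NULL) {
  if (!file.exists(path)) ff_abort_format(sprintf("No such file: %s", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      species = readr::col_character(),
      date = readr::col_character(),
      lon = readr::col_double(),
      lat = readr::col_double()
    ),
    progress = FALSE
  )
  need <- c("species", "date", "lon", "lat")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    ff_abort_format(sprintf(
      "Sightings file lacks column(s): %s.", paste(miss, collapse = ", ")
    ))
  }
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", raw$date)
  parsed <- as.Date(ifelse(iso, raw$date, NA), format = "%Y-%m-%d")
  bad <- which(is.na(parsed) & !is.na(raw$date) | is.na(raw$date))
  if (nrow(raw) > 0 && length(bad) > 0) {
    ff_abort_format(sprintf(
      "Unparseable date(s) at line %s of %s.",
      paste(bad + 1L, collapse = ", "), path  # +1 for the header line
    ))
  }
  out <- raw |> mutate(date = parsed)
  if (!is.null(species_filter)) {
    out <- out |> filter(species == species_filter)
  }
  if (any(!is.finite(out$lon) | !is.finite(out$lat))) {
    ff_abort_data("Sighting coordinates must be finite.")
  }
  out
}

#' @rdname read_sightings_csv
#' @param sightings A sightings tibble (columns species, date, lon, lat).
#' @export
write_sightings_csv <- function(sightings, path) {
  readr::write_csv(
    sightings[, c("species", "date", "lon", "lat")], path, progress = FALSE
  )
  invisible(path)
}
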