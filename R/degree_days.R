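#' Daily degree-day contribution above a base temperature
#'
#' Computes the daily contribution to cumulative degree-days from daily
#' maximum and minimum temperature with the four-branch weighted formula
#' (with `tmean = 0.5 * (tmax + tmin)`):
#'
#' \deqn{\Delta DD = \begin{cases}
#'   0 & T_{max} \le T_0 \\
#'   T_{mean} - T_0 & T_{min} \ge T_0 \\
#'   0.5\,(T_{max} - T_0) - 0.25\,(T_0 - T_{min}) & T_{mean} \ge T_0,\ T_{min} < T_0 \\
#'   0.25\,(T_{max} - T_0) & T_{mean} < T_0,\ T_{max} > T_0
#' \end{cases}}
#'
#' The result is non-negative for any `tmax >= tmin` and continuous across
#' all branch boundaries; branch selection uses exact comparisons (ties are
#' harmless by continuity). `NA` in either input yields `NA`.
#'
#' @param tmax,tmin Daily maximum/minimum temperature, degrees C. Vectors
#'   are recycled against each other; `tmax < tmin` is an error.
#' @param t0 Base (threshold) temperature, degrees C; scalar or vector
#'   recycled with the temperatures.
#' @return Numeric vector of daily degree-days (degC day).
#' @examples
#' daily_delta_dd(20, 10, 5.5)  # warm day: tmean - t0 = 9.5
#' daily_delta_dd(8, 0, 5.5)    # marginal day: 0.25 * (8 - 5.5)
#' @export
daily_delta_dd <- function(tmax, tmin, t0) {
  n <- max(length(tmax), length(tmin), length(t0))
  tmax <- rep_len(tmax, n)
  tmin <- rep_len(tmin, n)
  t0 <- rep_len(t0, n)
  both <- !is.na(tmax) & !is.na(tmin)
  if (any(tmax[both] < tmin[both])) {
    ff_abort_data("`tmax` must be >= `tmin`.")
  }
  tmean <- 0.5 * (tmax + tmin)
  dd <- 0.25 * (tmax - t0)                              # tmean < t0 & tmax > t0
  b3 <- both & tmean >= t0 & tmin < t0
  dd[b3] <- 0.5 * (tmax[b3] - t0[b3]) - 0.25 * (t0[b3] - tmin[b3])
  b2 <- both & tmin >= t0
  dd[b2] <- tmean[b2] - t0[b2]
  dd[both & tmax <= t0] <- 0
  dd[!both] <- NA_real_
  dd
}

#' Accumulate degree-days per cell and year
#'
#' Computes the cumulative degree-day series for each grid cell and calendar
#' year, starting on January 1 with no carry-over between years. Cell-years
#' with any missing day or missing temperature value in the calendar year
#' are excluded entirely (and counted in a message); no gap-filling is done.
#' Leap days are included, so series have length 365 or 366.
#'
#' @param temps A temperature table (see [validate_temperature_grid()]).
#' @param t0 Base temperature(s), degrees C; one accumulation per value.
#' @param quiet Suppress the exclusion message.
#' @return A tibble with columns `t0`, `lon_index`, `lat_index`, `year`,
#'   `day_of_year`, `cum_dd`; `cum_dd` is non-decreasing within each
#'   cell-year.
#' @export
accumulate_dd <- function(temps, t0, quiet = FALSE) {
  stopifnot(is.numeric(t0), length(t0) >= 1)
  parts <- date_parts(temps$date)
  base <- as_tibble(temps) |>
    mutate(year = parts$year, day_of_year = parts$doy) |>
    arrange(lon_index, lat_index, year, day_of_year)

  status <- base |>
    group_by(lon_index, lat_index, year) |>
    summarise(
      complete = dplyr::n() == days_in_year(year[1]) &&
        !anyNA(tmax) && !anyNA(tmin),
      .groups = "drop"
    )
  n_bad <- sum(!status$complete)
  if (n_bad > 0 && !quiet) {
    inform(sprintf(
      "accumulate_dd: excluded %d incomplete cell-year(s) (missing days or values).",
      n_bad
    ))
  }
  keep <- base |>
    inner_join(filter(status, complete), by = c("lon_index", "lat_index", "year"))

  purrr::map(t0, function(th) {
    keep |>
      mutate(t0 = th, delta = daily_delta_dd(tmax, tmin, th)) |>
      group_by(lon_index, lat_index, year) |>
      mutate(cum_dd = cumsum(delta)) |>
      ungroup() |>
      select(t0, lon_index, lat_index, year, day_of_year, cum_dd)
  }) |>
    purrr::list_rbind()
}

#' Regional average of cumulative degree-day series
#'
#' Averages the per-cell cumulative degree-day values of each day across all
#' member cells of each region (the average is over degree-day values, not
#' over temperatures). This daily regional-average table is the look-up
#' basis for the first-flight model.
#'
#' @param cell_dd Output of [accumulate_dd()].
#' @param regions Region membership tibble (`region`, `lon_index`,
#'   `lat_index`).
#' @return A tibble with columns `region`, `t0`, `year`, `day_of_year`,
#'   `cum_dd` (day-wise mean across member cells), and `n_cells`.
#' @export
regional_average_dd <- function(cell_dd, regions) {
  regions <- validate_regions(regions)
  joined <- inner_join(
    cell_dd, regions,
    by = c("lon_index", "lat_index"), relationship = "many-to-many"
  )
  if (nrow(joined) == 0) {
    ff_abort_data("No degree-day series fall inside the given regions.")
  }
  joined |>
    group_by(region, t0, year, day_of_year) |>
    summarise(
      cum_dd = mean(cum_dd),
      n_cells = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(region, t0, year, day_of_year)
}

#' Regional degree-day tables across a base-temperature scan
#'
#' Builds the regional-average cumulative degree-day table for every base
#' temperature in an arithmetic scan (default 0 to 10 degrees C in steps of
#' 0.5, i.e. 21 values).
#'
#' @inheritParams accumulate_dd
#' @inheritParams regional_average_dd
#' @param t0_min,t0_max,t0_step Scan range and step, degrees C.
#' @return A regional degree-day tibble as in [regional_average_dd()], with
#'   one block per scanned `t0`.
#' @export
t0_scan <- function(temps, regions, t0_min = 0, t0_max = 10, t0_step = 0.5,
                    quiet = FALSE) {
  if (t0_step <= 0) ff_abort_config("`t0_step` must be positive.")
  if (t0_min > t0_max) ff_abort_config("`t0_min` must be <= `t0_max`.")
  t0s <- seq(t0_min, t0_max, by = t0_step)
  purrr::map(t0s, function(th) {
    regional_average_dd(accumulate_dd(temps, th, quiet = quiet), regions)
  }) |>
    purrr::list_rbind()
}

#' Degree-days accumulated to a fixed calendar window
#'
#' Evaluates cumulative degree-day series at a fixed end date within each
#' year: either a month-day such as `"07-31"` (day-of-year 212, or 213 in
#' leap years) or `"annual"` for the last day of the year.
#'
#' @param dd A degree-day table with columns `year`, `day_of_year`,
#'   `cum_dd` (per-cell from [accumulate_dd()] or regional from
#'   [regional_average_dd()]); any other columns are kept as identifiers.
#' @param end `"annual"` or a `"MM-DD"` string.
#' @return The input rows at the window end day, with the `day_of_year`
#'   column replaced by a `window` label.
#' @export
fixed_window_dd <- function(dd, end = "07-31") {
  stopifnot(is.character(end), length(end) == 1)
  years <- unique(dd$year)
  if (identical(end, "annual")) {
    end_doy <- stats::setNames(days_in_year(years), years)
  } else {
    probe <- as.Date(sprintf("2001-%s", end), format = "%Y-%m-%d")
    if (is.na(probe)) {
      ff_abort_config(sprintf("`end` must be 'annual' or 'MM-DD', got '%s'.", end))
    }
    end_doy <- stats::setNames(
      date_parts(as.Date(sprintf("%d-%s", years, end)))$doy, years
    )
  }
  out <- dd |>
    mutate(.end_doy = unname(end_doy[as.character(year)])) |>
    filter(day_of_year == .end_doy) |>
    select(-.end_doy, -day_of_year) |>
    mutate(window = end, .before = cum_dd)
  expected <- dd |> distinct(across(-c(day_of_year, cum_dd)))
  if (nrow(out) < nrow(expected)) {
    ff_abort_data("Some series do not reach the requested window end day.")
  }
  out
}

#' Read and write regional degree-day tables
#'
#' CSV with columns `region`, `t0`, `year`, `day_of_year`, `cum_dd`: the
#' portable daily regional-average cumulative degree-day artifact.
#'
#' @param dd_table A regional degree-day tibble.
#' @param path File path.
#' @return `read_regional_dd()` returns the tibble; the writer returns
#'   `path` invisibly.
#' @export
write_regional_dd <- function(dd_table, path) {
  readr::write_csv(
    dd_table[, c("region", "t0", "year", "day_of_year", "cum_dd")],
    path, progress = FALSE
  )
  invisible(path)
}

#' @rdname write_regional_dd
#' @export
read_regional_dd <- function(path) {
  if (!file.exists(path)) ff_abort_format(sprintf("No such file: %s", path))
  readr::read_csv(
    path,
    col_types = readr::cols(
      region = readr::col_character(),
      t0 = readr::col_double(),
      year = readr::col_integer(),
      day_of_year = readr::col_integer(),
      cum_dd = readr::col_double()
    ),
    progress = FALSE
  )
}
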