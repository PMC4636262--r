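#' Period mean of modeled first-flight dates
#'
#' Averages the modeled regional first-flight date over the years of a
#' climate period (inclusive year range). Years in which the degree-day
#' constant is never reached are excluded from the mean and counted.
#'
#' @param dd_table A regional degree-day table covering all period years.
#' @param dd_c Degree-day constant.
#' @param period Length-2 integer vector `c(start_year, end_year)`.
#' @param quiet Suppress the not-reached message.
#' @return A tibble `region`, `t0`, `dd_c`, `mean_ff`, `n_years`,
#'   `n_not_reached`.
#' @export
period_mean_ff <- function(dd_table, dd_c, period, quiet = FALSE) {
  period <- as.integer(period)
  if (length(period) != 2 || period[1] > period[2]) {
    ff_abort_config("`period` must be c(start_year, end_year) with start <= end.")
  }
  years <- period[1]:period[2]
  tab <- dd_table |> filter(year %in% years)
  have <- tab |> distinct(region, t0, year) |> count(region, t0)
  if (nrow(have) == 0 || any(have$n < length(years))) {
    ff_abort_data("Degree-day table does not cover all period years.")
  }
  md <- model_ff_dates(tab, dd_c)
  out <- md |>
    group_by(region, t0, dd_c) |>
    summarise(
      mean_ff = mean(model_ff, na.rm = TRUE),
      n_years = sum(!is.na(model_ff)),
      n_not_reached = sum(is.na(model_ff)),
      .groups = "drop"
    )
  if (any(out$n_years == 0)) {
    ff_abort_data("DD_C never reached in any period year for some region/t0.")
  }
  if (!quiet && any(out$n_not_reached > 0)) {
    inform(sprintf(
      "period_mean_ff: %d region-t0 group(s) had not-reached years excluded.",
      sum(out$n_not_reached > 0)
    ))
  }
  out
}

#' First-flight advancement between two periods
#'
#' Difference of period mean modeled first-flight dates, period 1 minus
#' period 2: positive values mean earlier first flight in the later period
#' (advancement under warming).
#'
#' @inheritParams period_mean_ff
#' @param period1,period2 Length-2 integer vectors `c(start, end)`.
#' @return A tibble `region`, `t0`, `dd_c`, `mean_ff_p1`, `mean_ff_p2`,
#'   `advancement`.
#' @export
ff_advancement <- function(dd_table, dd_c, period1, period2, quiet = FALSE) {
  p1 <- period_mean_ff(dd_table, dd_c, period1, quiet = quiet) |>
    select(region, t0, dd_c, mean_ff_p1 = mean_ff)
  p2 <- period_mean_ff(dd_table, dd_c, period2, quiet = quiet) |>
    select(region, t0, dd_c, mean_ff_p2 = mean_ff)
  inner_join(p1, p2, by = c("region", "t0", "dd_c")) |>
    mutate(advancement = mean_ff_p1 - mean_ff_p2)
}

#' Change in regional mean temperature between two periods
#'
#' Difference (period 2 minus period 1) of the regional mean of daily mean
#' temperature `0.5 * (tmax + tmin)`, averaged over days, cells and years.
#' Cell-years with missing days or values are excluded and counted.
#'
#' @param temps A temperature table.
#' @param regions Region membership tibble.
#' @param period1,period2 Length-2 integer vectors `c(start, end)`.
#' @param quiet Suppress the exclusion message.
#' @return A tibble `region`, `tmean_p1`, `tmean_p2`, `delta_t`.
#' @export
period_temperature_change <- function(temps, regions, period1, period2,
                                      quiet = FALSE) {
  regions <- validate_regions(regions)
  parts <- date_parts(temps$date)
  x <- as_tibble(temps) |>
    mutate(year = parts$year) |>
    inner_join(regions, by = c("lon_index", "lat_index"),
               relationship = "many-to-many")
  status <- x |>
    group_by(region, lon_index, lat_index, year) |>
    summarise(
      complete = dplyr::n() == days_in_year(year[1]) &&
        !anyNA(tmax) && !anyNA(tmin),
      .groups = "drop"
    )
  n_bad <- sum(!status$complete)
  if (n_bad > 0 && !quiet) {
    inform(sprintf(
      "period_temperature_change: excluded %d incomplete cell-year(s).", n_bad
    ))
  }
  x <- x |>
    inner_join(filter(status, complete),
               by = c("region", "lon_index", "lat_index", "year"))
  pmean <- function(period, label) {
    years <- period[1]:period[2]
    sub <- x |> filter(year %in% years)
    if (nrow(sub) == 0) ff_abort_data("No temperature data in a period.")
    sub |>
      group_by(region) |>
      summarise("{label}" := mean(0.5 * (tmax + tmin)), .groups = "drop")
  }
  inner_join(
    pmean(as.integer(period1), "tmean_p1"),
    pmean(as.integer(period2), "tmean_p2"),
    by = "region"
  ) |>
    mutate(delta_t = tmean_p2 - tmean_p1)
}

#' Change in fixed-window degree-days between two periods
#'
#' Difference (period 2 minus period 1) of the period means of regional
#' degree-days accumulated to fixed calendar windows, for every base
#' temperature in the table. Defaults to the mid-summer window (to July 31)
#' and the whole year.
#'
#' @param dd_table A regional degree-day table.
#' @param period1,period2 Length-2 integer vectors `c(start, end)`.
#' @param windows Character vector of window ends (`"MM-DD"` or
#'   `"annual"`).
#' @return A tibble `region`, `t0`, `window`, `dd_p1`, `dd_p2`, `delta_dd`.
#' @export
period_dd_change <- function(dd_table, period1, period2,
                             windows = c("07-31", "annual")) {
  period1 <- as.integer(period1)
  period2 <- as.integer(period2)
  purrr::map(windows, function(w) {
    wd <- fixed_window_dd(dd_table, w)
    pmean <- function(period, label) {
      sub <- wd |> filter(year %in% period[1]:period[2])
      if (nrow(sub) == 0) ff_abort_data("No degree-day data in a period.")
      sub |>
        group_by(region, t0) |>
        summarise("{label}" := mean(cum_dd), .groups = "drop")
    }
    inner_join(pmean(period1, "dd_p1"), pmean(period2, "dd_p2"),
               by = c("region", "t0")) |>
      mutate(window = w, .after = t0) |>
      mutate(delta_dd = dd_p2 - dd_p1)
  }) |>
    purrr::list_rbind()
}

#' Two-period first-flight and climate change assessment
#'
#' Combines, per calibrated model (region, assumption, `t0`, `dd_c`), the
#' period mean modeled first-flight dates and their advancement, and, when
#' temperatures are supplied, the regional mean temperature change. When a
#' `dd_range` (per-case min/max of best constants) is supplied, the
#' advancement is also evaluated at the range limits, bracketing the
#' mid-range result.
#'
#' @param dd_table A regional degree-day table covering both periods and the
#'   model base temperatures.
#' @param models A tibble `assumption`, `region`, `t0`, `dd_c`.
#' @param period1,period2 Length-2 integer vectors `c(start, end)`.
#' @param temps Optional temperature table for the temperature change
#'   column.
#' @param regions Region membership (required with `temps`).
#' @param quiet Passed through to the component computations.
#' @return A tibble with one row per model: period mean FF dates,
#'   `advancement` (days, positive = earlier), and `delta_t` (degrees C)
#'   when temperatures were given.
#' @export
assess_change <- function(dd_table, models, period1, period2,
                          temps = NULL, regions = NULL, quiet = FALSE) {
  out <- purrr::pmap(
    models[, c("assumption", "region", "t0", "dd_c")],
    function(assumption, region, t0, dd_c) {
      a <- assumption; r <- region; th <- t0
      tab <- dd_table[dd_table$region == r & dd_table$t0 == th, ]
      if (nrow(tab) == 0) {
        ff_abort_data(sprintf("No degree-day table for %s at t0 = %g.", r, th))
      }
      ff_advancement(tab, dd_c, period1, period2, quiet = quiet) |>
        mutate(assumption = a, .before = 1)
    }
  ) |>
    purrr::list_rbind()
  if (!is.null(temps)) {
    if (is.null(regions)) ff_abort_config("`regions` is required with `temps`.")
    dt <- period_temperature_change(temps, regions, period1, period2,
                                    quiet = quiet)
    out <- left_join(out, select(dt, region, delta_t), by = "region")
  }
  out
}

#' Plot first-flight advancement per region
#'
#' Bar chart of modeled first-flight advancement (days, positive = earlier)
#' per region and observation assumption, as produced by [assess_change()].
#'
#' @param change Output of [assess_change()].
#' @return A ggplot object.
#' @export
plot_ff_advancement <- function(change) {
  ggplot(change, aes(x = region, y = advancement, fill = assumption)) +
    geom_col(position = "dodge") +
    labs(y = "FF advancement (days, positive = earlier)", x = NULL,
         fill = "assumption") +
    theme_minimal()
}
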