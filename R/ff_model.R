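#' First crossing of a cumulative degree-day series
#'
#' The modeled first-flight date for a candidate degree-day constant is the
#' smallest day on which the (non-decreasing) cumulative series reaches the
#' constant: no sub-day interpolation, ties at exact equality take the first
#' qualifying day. Series that never reach the constant return `NA`
#' ("not reached" is a value, not an error).
#'
#' @param cum_dd Non-decreasing numeric vector of cumulative degree-days.
#' @param dd_c Degree-day constant to reach.
#' @param day_of_year Optional day labels aligned with `cum_dd`; defaults to
#'   `1:length(cum_dd)`.
#' @return The day-of-year of first crossing, or `NA_integer_`.
#' @examples
#' first_crossing(cumsum(rep(1, 365)), 100.5)  # day 101
#' @export
first_crossing <- function(cum_dd, dd_c, day_of_year = seq_along(cum_dd)) {
  i <- match(TRUE, cum_dd >= dd_c)
  if (is.na(i)) NA_integer_ else as.integer(day_of_year[i])
}

#' Modeled first-flight dates from a regional degree-day table
#'
#' @param dd_table A regional degree-day table ([regional_average_dd()]).
#' @param dd_c Degree-day constant.
#' @return A tibble `region`, `t0`, `year`, `dd_c`, `model_ff` (day-of-year
#'   of first crossing; `NA` when not reached within the year).
#' @export
model_ff_dates <- function(dd_table, dd_c) {
  stopifnot(is.numeric(dd_c), length(dd_c) == 1, dd_c > 0)
  dd_table |>
    group_by(region, t0, year) |>
    summarise(
      model_ff = first_crossing(cum_dd, dd_c, day_of_year),
      .groups = "drop"
    ) |>
    mutate(dd_c = dd_c, .after = t0)
}

#' Root mean square error between modeled and observed annual dates
#'
#' Joins two year-indexed day series and returns the RMSE in days over the
#' common years; years missing on either side are skipped.
#'
#' @param modeled,observed Data frames with a `year` column plus exactly one
#'   other numeric column holding the day-of-year values.
#' @return RMSE in days (single number).
#' @examples
#' m <- tibble::tibble(year = 1:2, day = c(103, 96))
#' o <- tibble::tibble(year = 1:2, day = c(100, 100))
#' rmse_days(m, o)  # sqrt((9 + 16) / 2)
#' @export
rmse_days <- function(modeled, observed) {
  day_col <- function(df, what) {
    cand <- setdiff(names(df), "year")
    cand <- cand[vapply(df[cand], is.numeric, logical(1))]
    if (length(cand) != 1) {
      ff_abort_format(sprintf(
        "`%s` must have a `year` column and exactly one numeric day column.",
        what
      ))
    }
    cand
  }
  mc <- day_col(modeled, "modeled")
  oc <- day_col(observed, "observed")
  j <- inner_join(
    stats::setNames(modeled[, c("year", mc)], c("year", ".m")),
    stats::setNames(observed[, c("year", oc)], c("year", ".o")),
    by = "year"
  )
  j <- j[!is.na(j$.m) & !is.na(j$.o), ]
  if (nrow(j) == 0) ff_abort_data("No common years between modeled and observed.")
  sqrt(mean((j$.m - j$.o)^2))
}

#' Primary search range for the degree-day constant
#'
#' For every FF observation, evaluates the regional-average cumulative
#' degree-day series at the observation's FF day, averages those values per
#' year across observations, and returns the minimum, mean and maximum over
#' years with FF data. This bracket is the primary range of candidate
#' degree-day constants; the RMSE-minimizing constant is expected to fall
#' inside it.
#'
#' @param ff An FF tibble from [build_ff_dataset()].
#' @param dd_table A regional degree-day table covering all observation
#'   years (one or more `t0` values).
#' @return A tibble `assumption`, `region`, `t0`, `ddc_min`, `ddc_mean`,
#'   `ddc_max`, `n_years`.
#' @export
primary_ddc_range <- function(ff, dd_table) {
  if (nrow(ff) == 0) ff_abort_data("FF dataset is empty.")
  covered <- dd_table |> distinct(region, year)
  missing <- ff |>
    distinct(region, year) |>
    anti_join(covered, by = c("region", "year"))
  if (nrow(missing) > 0) {
    ff_abort_data(sprintf(
      "Degree-day table lacks %d observation region-year(s), e.g. %s %d.",
      nrow(missing), missing$region[1], missing$year[1]
    ))
  }
  ff |>
    inner_join(dd_table, by = c("region", "year", "day_of_year"),
               relationship = "many-to-many") |>
    group_by(assumption, region, t0, year) |>
    summarise(value = mean(cum_dd), .groups = "drop") |>
    group_by(assumption, region, t0) |>
    summarise(
      ddc_min = min(value), ddc_mean = mean(value), ddc_max = max(value),
      n_years = dplyr::n(), .groups = "drop"
    )
}

## internal: RMSE curve for one (assumption, region, t0) group ---------------
calibrate_group <- function(obs, cum_by_year, ddc_grid, max_unreached = 0.5) {
  years <- obs$year
  n_years <- length(years)
  eval_grid <- function(grid) {
    purrr::map_dfr(grid, function(ddc) {
      md <- vapply(
        cum_by_year,
        function(g) first_crossing(g$cum_dd, ddc, g$day_of_year),
        integer(1)
      )[as.character(years)]
      reached <- !is.na(md)
      n_used <- sum(reached)
      if (n_used == 0 || (n_years - n_used) / n_years > max_unreached) {
        tibble(dd_c = ddc, rmse = Inf, n_years = n_used, valid = FALSE)
      } else {
        tibble(
          dd_c = ddc,
          rmse = sqrt(mean((md[reached] - obs$mean_ff[reached])^2)),
          n_years = n_used, valid = TRUE
        )
      }
    })
  }
  curve <- eval_grid(ddc_grid)
  ok <- which(curve$valid)
  if (length(ok) > 0) {
    best_i <- ok[which.min(curve$rmse[ok])]
    span <- max(ddc_grid) - min(ddc_grid)
    step <- if (length(ddc_grid) > 1) ddc_grid[2] - ddc_grid[1] else 1
    if (span > 0 && best_i %in% c(1L, nrow(curve))) {
      warn("calibrate_ff_model: RMSE minimum on search boundary; extending range once.")
      ext <- if (best_i == 1L) {
        seq(min(ddc_grid) - span, min(ddc_grid) - step, by = step)
      } else {
        seq(max(ddc_grid) + step, max(ddc_grid) + span, by = step)
      }
      ext <- ext[ext > 0]
      if (length(ext) > 0) {
        curve <- bind_rows(curve, eval_grid(ext)) |> arrange(dd_c)
      }
    }
  }
  curve
}

#' Calibrate the first-flight degree-day model
#'
#' For each region, observation assumption and base temperature present in
#' the inputs, scans candidate degree-day constants, computes the RMSE of
#' the modeled regional first-flight dates against the observed regional
#' annual means over all years with FF data, and selects the RMSE-minimizing
#' constant. Candidates for which more than `max_unreached` of the years
#' never reach the constant are marked invalid and excluded from the
#' arg-min. When the minimum falls on a search boundary the range is
#' extended once (with a warning). Equal-RMSE ties resolve to the smaller
#' constant; across base temperatures, the best model is the global
#' minimizer with ties broken by smaller `t0`, then smaller `dd_c`.
#'
#' By default the candidate grid spans the per-group primary range
#' ([primary_ddc_range()]) extended by 20% on each side, in steps of
#' `ddc_step` (default 1 degree-day: calibrated constants are reported at
#' integer resolution).
#'
#' @param ff An FF tibble from [build_ff_dataset()] (either assumption or
#'   both bound together).
#' @param dd_table A regional degree-day table covering all observation
#'   years, with one block per candidate base temperature.
#' @param ddc_grid Optional explicit numeric vector of candidate constants;
#'   overrides the primary-range default.
#' @param ddc_step Grid step in degree-days.
#' @param extend Fractional extension of the primary range on each side.
#' @param max_unreached Maximum tolerated fraction of not-reached years per
#'   candidate.
#' @return An object of class `ff_calibration`: a list with `curves` (all
#'   evaluated candidates), `minima` (per assumption/region/t0 arg-min),
#'   `best` (per assumption/region global best), `observed` (the regional
#'   annual mean FF used) and `settings`. Use [tidy()] for the curves,
#'   [glance()] for the best models, [autoplot()] for the RMSE curves.
#' @export
calibrate_ff_model <- function(ff, dd_table, ddc_grid = NULL, ddc_step = 1,
                               extend = 0.2, max_unreached = 0.5) {
  observed <- regional_annual_mean_ff(ff)
  ranges <- primary_ddc_range(ff, dd_table)
  groups <- observed |> distinct(assumption, region)
  t0s <- sort(unique(dd_table$t0))

  curves <- purrr::pmap(
    tidyr::expand_grid(groups, t0 = t0s),
    function(assumption, region, t0) {
      a <- assumption; r <- region; th <- t0
      obs <- observed[observed$assumption == a & observed$region == r, ]
      tab <- dd_table[dd_table$region == r & dd_table$t0 == th, ]
      cum_by_year <- split(
        tab[, c("day_of_year", "cum_dd")],
        tab$year
      )
      grid <- ddc_grid
      if (is.null(grid)) {
        pr <- ranges[ranges$assumption == a & ranges$region == r &
                       ranges$t0 == th, ]
        lo <- max(ddc_step, floor(pr$ddc_min * (1 - extend)))
        hi <- ceiling(pr$ddc_max * (1 + extend))
        grid <- seq(lo, hi, by = ddc_step)
      }
      calibrate_group(obs, cum_by_year, grid, max_unreached) |>
        mutate(assumption = a, region = r, t0 = th, .before = 1)
    }
  ) |>
    purrr::list_rbind()

  minima <- curves |>
    filter(valid) |>
    group_by(assumption, region, t0) |>
    arrange(rmse, dd_c, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(assumption, region, t0, dd_c, rmse, n_years)

  best <- select_best_model(minima)

  structure(
    list(
      curves = curves, minima = minima, best = best, observed = observed,
      settings = list(
        ddc_step = ddc_step, extend = extend, max_unreached = max_unreached,
        t0_values = t0s, explicit_grid = !is.null(ddc_grid)
      )
    ),
    class = "ff_calibration"
  )
}

#' Select the globally best model across base-temperature scenarios
#'
#' @param minima A tibble of per-`t0` RMSE minima (`assumption`, `region`,
#'   `t0`, `dd_c`, `rmse`, ...).
#' @return One row per assumption and region: the global RMSE minimizer,
#'   ties broken by smaller `t0` then smaller `dd_c`.
#' @export
select_best_model <- function(minima) {
  if (nrow(minima) == 0) ff_abort_data("No valid calibration minima.")
  minima |>
    group_by(assumption, region) |>
    arrange(rmse, t0, dd_c, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' @export
print.ff_calibration <- function(x, ...) {
  cat("<ff_calibration>\n")
  cat(sprintf(
    "  %d RMSE curve(s) over t0 in {%s}\n",
    nrow(distinct(x$curves, assumption, region, t0)),
    paste(x$settings$t0_values, collapse = ", ")
  ))
  cat("  Best models:\n")
  print(as.data.frame(x$best), row.names = FALSE)
  invisible(x)
}

#' @rdname calibrate_ff_model
#' @param x,object An `ff_calibration` object.
#' @param ... Unused.
#' @method tidy ff_calibration
#' @export
tidy.ff_calibration <- function(x, ...) x$curves

#' @rdname calibrate_ff_model
#' @method glance ff_calibration
#' @export
glance.ff_calibration <- function(x, ...) x$best

#' @rdname calibrate_ff_model
#' @method autoplot ff_calibration
#' @export
autoplot.ff_calibration <- function(object, ...) {
  ggplot(
    filter(object$curves, valid),
    aes(x = dd_c, y = rmse, colour = factor(t0))
  ) +
    geom_line() +
    geom_point(
      data = object$minima,
      aes(x = dd_c, y = rmse, colour = factor(t0)),
      shape = 4, size = 2.5, stroke = 1.2
    ) +
    facet_grid(assumption ~ region) +
    labs(
      x = expression(DD[C] ~ "(degree-days)"), y = "RMSE (days)",
      colour = expression(T[0] ~ (degree * C))
    ) +
    theme_minimal()
}

#' Cross-regional consistency of calibrated degree-day constants
#'
#' Summarizes how tightly the per-region best constants agree: for each case
#' (e.g. observation assumption) and pooled over all cases, reports the
#' mid-range `(min + max) / 2`, the half-range `(max - min) / 2`, and the
#' half-range as a percentage of the mid-range, both unrounded and rounded
#' to the nearest integer percent.
#'
#' @param best A tibble with one calibrated value per region and case.
#' @param value Column holding the calibrated constants (default `dd_c`).
#' @param case Column defining the cases (default `assumption`).
#' @return A tibble with one row per case plus a `"pooled"` row: `case`,
#'   `n`, `ddc_min`, `ddc_max`, `mid_range`, `half_range`,
#'   `half_range_pct`, `half_range_pct_int`.
#' @examples
#' best <- tibble::tibble(
#'   assumption = rep(c("sva", "oba"), each = 3),
#'   dd_c = c(167, 184, 188, 147, 159, 153)
#' )
#' consistency_metrics(best)
#' @export
consistency_metrics <- function(best, value = "dd_c", case = "assumption") {
  v <- best[[value]]
  cs <- best[[case]]
  if (is.null(v) || is.null(cs)) {
    ff_abort_format("`best` must contain the value and case columns.")
  }
  if (any(table(cs) < 2)) {
    ff_abort_data("Each case needs at least two regional values.")
  }
  one <- function(vals, label) {
    mid <- (min(vals) + max(vals)) / 2
    half <- (max(vals) - min(vals)) / 2
    pct <- 100 * half / mid
    tibble(
      case = label, n = length(vals),
      ddc_min = min(vals), ddc_max = max(vals),
      mid_range = mid, half_range = half,
      half_range_pct = pct, half_range_pct_int = round(pct)
    )
  }
  bind_rows(
    purrr::imap(split(v, cs), ~ one(.x, .y)) |> purrr::list_rbind(),
    one(v, "pooled")
  )
}

#' Point test of a calibrated regional model
#'
#' Tests the predictive capability of best regional models against the
#' individual sightings: the model first-flight for each grid cell and year
#' is the first crossing of that cell's own cumulative degree-day series,
#' and the RMSE is computed over all point observations (each compared to
#' its own cell-year model value). Observations whose cell-year series never
#' reaches the constant are excluded, with counts reported.
#'
#' @param ff An FF tibble.
#' @param cell_dd Per-cell degree-day series ([accumulate_dd()]) covering
#'   the model base temperatures.
#' @param models A tibble of models: `assumption`, `region`, `t0`, `dd_c`
#'   (e.g. `glance()` of an [calibrate_ff_model()] fit).
#' @param quiet Suppress the exclusion message.
#' @return A tibble `assumption`, `region`, `t0`, `dd_c`, `rmse`, `n_obs`,
#'   `n_excluded`.
#' @export
point_test <- function(ff, cell_dd, models, quiet = FALSE) {
  res <- purrr::pmap(
    models[, c("assumption", "region", "t0", "dd_c")],
    function(assumption, region, t0, dd_c) {
      a <- assumption; r <- region; th <- t0; ddc <- dd_c
      obs <- ff[ff$assumption == a & ff$region == r, ]
      if (nrow(obs) == 0) ff_abort_data(sprintf("No FF data for %s/%s.", a, r))
      tab <- cell_dd[cell_dd$t0 == th, ]
      if (nrow(tab) == 0) {
        ff_abort_data(sprintf("Cell series lack t0 = %g.", th))
      }
      cell_ff <- tab |>
        semi_join(obs, by = c("lon_index", "lat_index", "year")) |>
        group_by(lon_index, lat_index, year) |>
        summarise(
          model_ff = first_crossing(cum_dd, ddc, day_of_year),
          .groups = "drop"
        )
      j <- inner_join(obs, cell_ff, by = c("lon_index", "lat_index", "year"))
      if (nrow(j) < nrow(obs)) {
        ff_abort_data("Cell degree-day series missing for some observations.")
      }
      reached <- !is.na(j$model_ff)
      if (!quiet && any(!reached)) {
        inform(sprintf(
          "point_test: %d observation(s) in cell-years not reaching DD_C excluded (%s/%s).",
          sum(!reached), a, r
        ))
      }
      if (!any(reached)) ff_abort_data("No cell-year reaches the constant.")
      tibble(
        assumption = a, region = r, t0 = th, dd_c = ddc,
        rmse = sqrt(mean((j$model_ff[reached] - j$day_of_year[reached])^2)),
        n_obs = sum(reached), n_excluded = sum(!reached)
      )
    }
  ) |>
    purrr::list_rbind()
  res
}
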