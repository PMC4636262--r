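# a regional table with cum_dd = 1, 2, ..., 365 for each requested year
ramp_table <- function(years = 2005, region = "R", t0 = 5.5, slope = 1) {
  tidyr::expand_grid(region = region, t0 = t0, year = years,
                     day_of_year = 1:365) |>
    dplyr::mutate(cum_dd = slope * day_of_year)
}

test_that("first crossing is the smallest qualifying day, NA when unreached", {
  cum <- cumsum(rep(1, 365))
  expect_equal(first_crossing(cum, 100), 100L)
  expect_equal(first_crossing(cum, 100.5), 101L)
  expect_true(is.na(first_crossing(cum, 400)))
  # monotone in dd_c
  dds <- sort(runif(50, 1, 360))
  days <- vapply(dds, function(d) first_crossing(cum, d), integer(1))
  expect_true(all(diff(days) >= 0))
})

test_that("model dates shift monotonically with t0 and under warming", {
  spec <- grid_spec(10, 55, 1, 1)
  sc <- climate_scenario(annual_mean = 7, seasonal_amplitude = 10,
                         years = 2004, seed = 5)
  temps <- simulate_temperature(sc, spec)
  reg <- all_cells_region(spec)
  tab <- t0_scan(temps, reg, 2, 8, 2, quiet = TRUE)
  days <- model_ff_dates(tab, 150) |> dplyr::arrange(t0)
  expect_true(all(diff(days$model_ff) >= 0))  # higher threshold -> later

  warm <- temps
  warm$tmax <- warm$tmax + 1
  warm$tmin <- warm$tmin + 1
  tab_w <- t0_scan(warm, reg, 2, 8, 2, quiet = TRUE)
  days_w <- model_ff_dates(tab_w, 150) |> dplyr::arrange(t0)
  expect_true(all(days_w$model_ff <= days$model_ff))  # warming never delays
})

test_that("rmse over common years matches hand values", {
  yrs <- 2001:2003
  obs <- tibble::tibble(year = yrs, day = c(100, 100, 100))
  expect_equal(rmse_days(obs, obs), 0)
  off <- tibble::tibble(year = yrs, day = c(103, 103, 103))
  expect_equal(rmse_days(off, obs), 3)
  two <- tibble::tibble(year = 2001:2002, day = c(103, 96))
  expect_equal(rmse_days(two, obs), sqrt((9 + 16) / 2))
  # years missing on one side are skipped; disjoint years error
  expect_equal(rmse_days(two, obs[1:2, ]), sqrt((9 + 16) / 2))
  expect_error(
    rmse_days(two, tibble::tibble(year = 2010, day = 100)),
    class = "ff_data_error"
  )
})

test_that("primary range brackets per-year mean degree-days at observed FF", {
  tab <- ramp_table(2005:2006)
  # 2005: obs at days 140, 160 -> mean 150; 2006: obs at day 160 -> 160
  ff <- make_ff(tibble::tibble(
    lon_index = c(0L, 1L, 0L), lat_index = 0L,
    year = c(2005L, 2005L, 2006L), day_of_year = c(140L, 160L, 160L)
  ))
  out <- primary_ddc_range(ff, tab)
  expect_equal(out$ddc_min, 150)
  expect_equal(out$ddc_mean, 155)
  expect_equal(out$ddc_max, 160)
  # observation year absent from the table errors
  expect_error(primary_ddc_range(ff, ramp_table(2005)),
               class = "ff_data_error")
})

test_that("calibration recovers an exactly-consistent constant with zero rmse", {
  tab <- ramp_table(2003:2010, slope = 2)   # crossing(ddc) = ceiling(ddc / 2)
  truth <- 160
  obs_days <- ceiling(truth / 2)
  ff <- make_ff(tibble::tibble(
    lon_index = 0L, lat_index = 0L, year = 2003:2010,
    day_of_year = as.integer(obs_days)
  ))
  fit <- calibrate_ff_model(ff, tab)
  best <- glance(fit)
  expect_equal(best$rmse, 0)
  # slope-2 ramp: every ddc in (158, 160] crosses on day 80; tie -> smallest on grid
  expect_equal(best$dd_c, 159)
  expect_true(all(tidy(fit)$valid))
})

test_that("shifting observations later weakly increases the calibrated constant", {
  spec <- grid_spec(10, 55, 1, 1)
  sc <- climate_scenario(annual_mean = 7, seasonal_amplitude = 10,
                         years = 2003:2008, seed = 9)
  temps <- simulate_temperature(sc, spec)
  tab <- regional_average_dd(accumulate_dd(temps, 5.5, quiet = TRUE),
                             all_cells_region(spec))
  base_days <- model_ff_dates(tab, 150)
  ff1 <- make_ff(tibble::tibble(
    lon_index = 0L, lat_index = 0L, year = base_days$year,
    day_of_year = as.integer(base_days$model_ff)
  ))
  ff2 <- dplyr::mutate(ff1, day_of_year = day_of_year + 5L)
  g1 <- seq(80, 300, 1)
  fit1 <- calibrate_ff_model(ff1, tab, ddc_grid = g1)
  fit2 <- calibrate_ff_model(ff2, tab, ddc_grid = g1)
  expect_gte(glance(fit2)$dd_c, glance(fit1)$dd_c)
})

test_that("unreachable candidates are invalid and boundary minima extend once", {
  tab <- ramp_table(2003:2006)  # max cum_dd = 365
  ff <- make_ff(tibble::tibble(
    lon_index = 0L, lat_index = 0L, year = 2003:2006, day_of_year = 150L
  ))
  fit <- suppressWarnings(calibrate_ff_model(ff, tab, ddc_grid = c(300, 400, 500)))
  curves <- tidy(fit)
  expect_false(any(curves$valid[curves$dd_c > 365]))
  expect_true(is.infinite(curves$rmse[curves$dd_c == 400]))
  # minimum at grid edge triggers a one-shot extension warning
  expect_warning(
    fit2 <- calibrate_ff_model(ff, tab, ddc_grid = c(200, 210, 220)),
    regexp = "boundary"
  )
  expect_lt(glance(fit2)$dd_c, 200)
})

test_that("best model selection breaks ties toward smaller t0 then dd_c", {
  minima <- tibble::tibble(
    assumption = "sva", region = "R",
    t0 = c(0, 5.5, 10), dd_c = c(300, 170, 40), rmse = c(6, 5, 5),
    n_years = 8L
  )
  best <- select_best_model(minima)
  expect_equal(best$t0, 5.5)
  expect_equal(best$dd_c, 170)
})

test_that("cross-regional consistency metrics reproduce mid-range arithmetic", {
  best <- tibble::tibble(
    assumption = rep(c("sva", "oba"), each = 3),
    dd_c = c(167, 184, 188, 147, 159, 153)
  )
  out <- consistency_metrics(best)
  sva <- out[out$case == "sva", ]
  oba <- out[out$case == "oba", ]
  pooled <- out[out$case == "pooled", ]
  expect_equal(sva$mid_range, 177.5)
  expect_equal(sva$half_range_pct_int, 6)
  expect_equal(oba$mid_range, 153)
  expect_equal(oba$half_range_pct_int, 4)
  expect_equal(pooled$half_range_pct_int, 12)
  # degenerate identical values
  same <- consistency_metrics(
    tibble::tibble(assumption = "x", dd_c = c(150, 150))
  )
  expect_equal(same$half_range_pct[same$case == "x"], 0)
  expect_error(
    consistency_metrics(tibble::tibble(assumption = "x", dd_c = 150)),
    class = "ff_data_error"
  )
})

test_that("point test compares each observation to its own cell-year model", {
  spec <- grid_spec(10, 55, 1, 1)
  temps <- make_const_temps(7.5, 7.5, years = 2005, spec = spec)  # 2 DD/day
  cell_dd <- accumulate_dd(temps, 5.5, quiet = TRUE)
  # model FF for ddc = 160 on a 2 DD/day cell: day 80
  ff <- make_ff(tibble::tibble(
    lon_index = 0L, lat_index = 0L, year = c(2005L, 2005L),
    day_of_year = c(83L, 77L)
  ))
  models <- tibble::tibble(assumption = "sva", region = "R", t0 = 5.5,
                           dd_c = 160)
  out <- point_test(ff, cell_dd, models, quiet = TRUE)
  expect_equal(out$rmse, 3)
  expect_equal(out$n_obs, 2)
  # exact observations give zero rmse
  exact <- make_ff(tibble::tibble(
    lon_index = 0L, lat_index = 0L, year = 2005L, day_of_year = 80L
  ))
  expect_equal(point_test(exact, cell_dd, models, quiet = TRUE)$rmse, 0)
  # unreached cell-years are excluded with a message
  far <- tibble::tibble(assumption = "sva", region = "R", t0 = 5.5,
                        dd_c = 1e6)
  expect_error(point_test(ff, cell_dd, far, quiet = TRUE),
               class = "ff_data_error")
})

test_that("calibration methods expose curves, best models and a plot", {
  tab <- ramp_table(2003:2006)
  ff <- make_ff(tibble::tibble(
    lon_index = 0L, lat_index = 0L, year = 2003:2006, day_of_year = 150L
  ))
  fit <- calibrate_ff_model(ff, tab)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_s3_class(glance(fit), "tbl_df")
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "Best models")
})
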