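test_that("temperature simulation is deterministic and structurally sound", {
  spec <- grid_spec(10, 55, 2, 2)
  sc <- climate_scenario(years = 2004:2005, seed = 77, cell_noise_sd = 0.4)
  a <- simulate_temperature(sc, spec)
  b <- simulate_temperature(sc, spec)
  expect_identical(a, b)
  expect_equal(nrow(a), 4 * (366 + 365))
  expect_equal(a$tmax - a$tmin, rep(sc$diurnal_range, nrow(a)))
  expect_silent(validate_temperature_grid(a, spec))
})

test_that("without noise or gradient all cells are identical", {
  spec <- grid_spec(10, 55, 2, 2)
  sc <- climate_scenario(daily_noise_sd = 0, cell_noise_sd = 0,
                         lat_gradient = 0, years = 2004, seed = 1)
  temps <- simulate_temperature(sc, spec)
  ref <- dplyr::filter(temps, lon_index == 0, lat_index == 0)
  for (i in 0:1) for (j in 0:1) {
    cell <- dplyr::filter(temps, lon_index == i, lat_index == j)
    expect_equal(cell$tmax, ref$tmax)
  }
})

test_that("simulated annual mean matches the scenario within Monte Carlo error", {
  spec <- grid_spec(10, 55, 2, 2)
  sc <- climate_scenario(annual_mean = 6.2, lat_gradient = 0,
                         daily_noise_sd = 2, cell_noise_sd = 0.5,
                         years = 2003:2006, seed = 13)
  temps <- simulate_temperature(sc, spec)
  tmean <- 0.5 * (temps$tmax + temps$tmin)
  # seasonal cosine over whole years averages out; noise SE governs the rest
  se <- sd(tmean) / sqrt(length(unique(temps$date)))  # days are shared draws
  expect_lt(abs(mean(tmean) - 6.2), 3 * max(se, 0.05))
})

test_that("latitudinal gradient shifts cell means as configured", {
  spec <- grid_spec(10, 55, 1, 3)
  sc <- climate_scenario(annual_mean = 6, lat_gradient = -0.8,
                         daily_noise_sd = 0, cell_noise_sd = 0,
                         years = 2005, seed = 2)
  temps <- simulate_temperature(sc, spec)
  cm <- temps |>
    dplyr::group_by(lat_index) |>
    dplyr::summarise(m = mean(0.5 * (tmax + tmin)), .groups = "drop")
  expect_equal(diff(cm$m), rep(-0.8 * 0.25, 2), tolerance = 1e-9)
  # centered on the reference latitude; the 365.25-day cosine leaves a
  # sub-0.01 C residual over a 365-day calendar year
  expect_lt(abs(mean(cm$m) - 6), 0.05)
})

test_that("SVA sightings without offsets sit exactly on the cells' true FF", {
  spec <- grid_spec(10, 55, 2, 1)
  sc <- climate_scenario(annual_mean = 8, seasonal_amplitude = 9,
                         cell_noise_sd = 0.5, years = 2003:2005, seed = 3)
  temps <- simulate_temperature(sc, spec)
  om <- observer_model("sva", sva_offset_sd = 0, observers_per_cell = 3,
                       seed = 4)
  sim <- simulate_sightings(temps, 160, 5.5, om)
  expect_equal(nrow(sim$sightings), 2 * 3 * 3)  # cells x years x observers
  got <- assign_cell(sim$sightings, spec)
  parts <- as.POSIXlt(got$date)
  got$year <- parts$year + 1900
  got$day <- parts$yday + 1
  j <- dplyr::inner_join(
    got, sim$truth$ff,
    by = c("lon_index", "lat_index", "year")
  )
  expect_equal(j$day, j$true_ff)
})

test_that("truth records agree with an independent first-crossing oracle", {
  spec <- grid_spec(10, 55, 2, 1)
  sc <- climate_scenario(annual_mean = 7, cell_noise_sd = 0.5,
                         years = 2004:2005, seed = 8)
  temps <- simulate_temperature(sc, spec)
  om <- observer_model("sva", seed = 9)
  sim <- simulate_sightings(temps, 150, 5.5, om)
  parts <- as.POSIXlt(temps$date)
  temps$year <- parts$year + 1900
  for (r in seq_len(nrow(sim$truth$ff))) {
    row <- sim$truth$ff[r, ]
    cell <- temps[temps$lon_index == row$lon_index &
                    temps$lat_index == row$lat_index &
                    temps$year == row$year, ]
    cell <- cell[order(cell$date), ]
    cum <- cumsum(vapply(
      seq_len(nrow(cell)),
      function(i) oracle_delta_dd(cell$tmax[i], cell$tmin[i], 5.5),
      numeric(1)
    ))
    expect_equal(row$true_ff, which(cum >= 150)[1])
  }
})

test_that("OBA sightings are delayed, never early, and earliest converges to truth", {
  spec <- grid_spec(10, 55, 2, 1)
  sc <- climate_scenario(annual_mean = 8, years = 2003:2006, seed = 5)
  temps <- simulate_temperature(sc, spec)
  om <- observer_model("oba", observers_per_cell = 4,
                       oba_delay = list(dist = "geometric", mean = 3),
                       seed = 6)
  sim <- simulate_sightings(temps, 160, 5.5, om)
  got <- assign_cell(sim$sightings, spec)
  parts <- as.POSIXlt(got$date)
  got$year <- parts$year + 1900
  got$day <- parts$yday + 1
  j <- dplyr::inner_join(got, sim$truth$ff,
                         by = c("lon_index", "lat_index", "year"))
  expect_true(all(j$day >= j$true_ff))

  # P(earliest = truth) grows with the number of observers
  hit_rate <- function(m, seeds) {
    mean(vapply(seeds, function(s) {
      om <- observer_model("oba", observers_per_cell = m, seed = s)
      sm <- simulate_sightings(temps, 160, 5.5, om)
      g <- assign_cell(sm$sightings, spec)
      p <- as.POSIXlt(g$date)
      g$year <- p$year + 1900
      g$day <- p$yday + 1
      e <- g |>
        dplyr::group_by(lon_index, lat_index, year) |>
        dplyr::summarise(day = min(day), .groups = "drop") |>
        dplyr::inner_join(sm$truth$ff,
                          by = c("lon_index", "lat_index", "year"))
      mean(e$day == e$true_ff)
    }, numeric(1)))
  }
  expect_gt(hit_rate(12, 1:3), hit_rate(1, 1:3))
})

test_that("delay-free OBA observers reproduce the truth exactly", {
  spec <- grid_spec(10, 55, 1, 1)
  sc <- climate_scenario(annual_mean = 8, years = 2004, seed = 10)
  temps <- simulate_temperature(sc, spec)
  om <- observer_model("oba", observers_per_cell = 2,
                       oba_delay = list(dist = "geometric", mean = 0),
                       seed = 11)
  sim <- simulate_sightings(temps, 160, 5.5, om)
  parts <- as.POSIXlt(sim$sightings$date)
  expect_true(all(parts$yday + 1 == sim$truth$ff$true_ff))
})

test_that("identical observer config and seed give identical sightings", {
  spec <- grid_spec(10, 55, 2, 1)
  sc <- climate_scenario(years = 2004:2005, seed = 20)
  temps <- simulate_temperature(sc, spec)
  om <- observer_model("sva", observers_per_cell = 3, seed = 21,
                       reporting_probability = 0.7)
  s1 <- simulate_sightings(temps, 150, 5.5, om)
  s2 <- simulate_sightings(temps, 150, 5.5, om)
  expect_identical(s1$sightings, s2$sightings)
})

test_that("SVA and OBA mechanisms separate as their assumptions predict", {
  spec <- grid_spec(10, 55, 3, 1)
  sc <- climate_scenario(annual_mean = 7, cell_noise_sd = 0.3,
                         years = 2003:2008, seed = 30)
  temps <- simulate_temperature(sc, spec)
  regions <- all_cells_region(spec)
  annual_means <- function(sim, assumption) {
    ded <- dedupe_location_year(sim$sightings)
    ff <- build_ff_dataset(ded, regions, spec, assumption, quiet = TRUE)
    regional_annual_mean_ff(ff)$mean_ff
  }
  # on SVA-generated data the OBA (earliest-only) view reads earlier dates
  sva_world <- simulate_sightings(
    temps, 160, 5.5,
    observer_model("sva", sva_offset_sd = 0.7, observers_per_cell = 5, seed = 31)
  )
  expect_true(all(annual_means(sva_world, "oba") <=
                    annual_means(sva_world, "sva")))
  # on OBA-generated data the earliest-only view is closer to the truth
  oba_world <- simulate_sightings(
    temps, 160, 5.5,
    observer_model("oba", observers_per_cell = 5, seed = 32)
  )
  truth_mean <- sva_world$truth$ff |>
    dplyr::group_by(year) |>
    dplyr::summarise(m = mean(true_ff), .groups = "drop")
  bias <- function(assumption) {
    mean(abs(annual_means(oba_world, assumption) - truth_mean$m))
  }
  expect_lte(bias("oba"), bias("sva"))
})

test_that("the packaged transect spans the configured climate gradient", {
  tr <- swedish_transect(years = 2004, seed = 1)
  expect_named(tr, c("Skane", "Sormland-Stockholm", "Medelpad-Angermanland"))
  means <- vapply(tr, function(r) r$scenario$annual_mean, numeric(1))
  expect_equal(unname(means), c(8.2, 6.9, 3.6))
  temps <- simulate_temperature(tr$Skane$scenario, tr$Skane$spec,
                                tr$Skane$cells)
  expect_equal(dplyr::n_distinct(temps$lon_index, temps$lat_index), 9)
})
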