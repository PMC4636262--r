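#' Read a run configuration file
#'
#' Run configurations are structured YAML files validated before any
#' computation; the same lists can be built directly in R and passed to
#' [run_simulation()], [run_calibration()] and [run_change()].
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) ff_abort_config(sprintf("No such config file: %s", path))
  yaml::read_yaml(path)
}

require_fields <- function(config, fields, where) {
  miss <- setdiff(fields, names(config))
  if (length(miss) > 0) {
    ff_abort_config(sprintf(
      "Config for %s lacks field(s): %s.", where, paste(miss, collapse = ", ")
    ))
  }
  invisible(config)
}

ensure_out_dir <- function(out_dir, quiet = FALSE) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    if (!quiet) inform(sprintf("Created output directory %s.", out_dir))
  }
  out_dir
}

write_manifest <- function(out_dir, config, seed = NULL) {
  manifest <- list(
    package = "firstflight",
    version = as.character(utils::packageVersion("firstflight")),
    seed = seed,
    config = config
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Simulate a synthetic study and write its input files
#'
#' Generates gridded daily temperatures, sighting records under both
#' observation mechanisms, and truth records for every region of a
#' scenario set, and writes them to disk in the exact formats the analysis
#' functions read. Reruns with the same configuration produce identical
#' files.
#'
#' Config fields: `out_dir`; `dd_c`, `t0` (truth); `years` (vector or
#' `list(from, to)`); `seed`; optional `warming`, `change_year`; optional
#' `observer` overrides (`observers_per_cell`, `reporting_probability`,
#' `sva_offset_sd`, `oba_delay_mean`); optional `species`.
#'
#' @param config A named list or the path to a YAML file.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named list of per-region output paths.
#' @export
run_simulation <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  require_fields(config, c("out_dir", "dd_c", "t0", "seed"), "run_simulation")
  years <- config$years %||% list(from = 2003, to = 2010)
  if (is.list(years)) years <- years$from:years$to
  seed <- as.integer(config$seed)
  species <- config$species %||% "Anthocharis cardamines"
  obs_cfg <- config$observer %||% list()

  transect <- swedish_transect(
    years = years, seed = seed,
    warming = config$warming %||% 0,
    change_year = config$change_year
  )
  out_dir <- ensure_out_dir(config$out_dir, quiet = quiet)

  paths <- purrr::imap(transect, function(rg, name) {
    rdir <- ensure_out_dir(file.path(out_dir, name), quiet = TRUE)
    temps <- simulate_temperature(rg$scenario, rg$spec, rg$cells)
    regions <- mutate(rg$cells, region = name, .before = 1)
    p <- list(
      temperature = file.path(rdir, "temperature.csv"),
      grid_spec = file.path(rdir, "grid_spec.json"),
      regions = file.path(rdir, "regions.json"),
      sightings_sva = file.path(rdir, "sightings_sva.csv"),
      sightings_oba = file.path(rdir, "sightings_oba.csv"),
      truth = file.path(rdir, "truth.json")
    )
    write_temperature_csv(temps, p$temperature)
    write_grid_spec(rg$spec, p$grid_spec)
    write_regions_json(regions, p$regions)
    sims <- purrr::map(c(sva = "sva", oba = "oba"), function(mode) {
      om <- observer_model(
        mode = mode,
        observers_per_cell = obs_cfg$observers_per_cell %||% 5,
        reporting_probability = obs_cfg$reporting_probability %||% 1,
        sva_offset_sd = obs_cfg$sva_offset_sd %||% 0.5,
        oba_delay = list(
          dist = obs_cfg$oba_delay_dist %||% "geometric",
          mean = obs_cfg$oba_delay_mean %||% 3
        ),
        seed = seed + 1000L * match(mode, c("sva", "oba")) +
          match(name, names(transect))
      )
      simulate_sightings(temps, config$dd_c, config$t0, om, species = species)
    })
    write_sightings_csv(sims$sva$sightings, p$sightings_sva)
    write_sightings_csv(sims$oba$sightings, p$sightings_oba)
    jsonlite::write_json(
      list(
        dd_c = config$dd_c, t0 = config$t0, region = name,
        true_ff = sims$sva$truth$ff
      ),
      p$truth, auto_unbox = TRUE, digits = NA, null = "null"
    )
    if (!quiet) inform(sprintf("Simulated region %s (%d cells).", name, nrow(rg$cells)))
    p
  })
  write_manifest(out_dir, config, seed)
  invisible(paths)
}

read_input_set <- function(input, species, quiet = FALSE) {
  require_fields(input, c("temperature", "grid_spec", "regions", "sightings"),
                 "calibration input")
  spec <- read_grid_spec(input$grid_spec)
  list(
    spec = spec,
    temps = read_temperature_csv(input$temperature, spec),
    regions = read_regions_json(input$regions, spec),
    sightings = read_sightings_csv(input$sightings, species)
  )
}

#' Run the calibration pipeline
#'
#' Reads temperatures, regions and sightings, deduplicates sightings to one
#' record per location-year, builds the per-assumption first-flight
#' datasets, computes regional degree-day tables for the configured base
#' temperatures, calibrates the degree-day constant per region and
#' assumption, and writes a calibration report (JSON), the RMSE curves
#' (CSV), the regional degree-day table (CSV) and a manifest.
#'
#' Config fields: `out_dir`; `inputs`: a list of input sets, each with
#' paths `temperature`, `grid_spec`, `regions`, `sightings` (for the OBA
#' and SVA views of the same sightings file, list it once; both assumptions
#' are built from it); optional `species`, `assumptions`, `t0_values`
#' (default 0, 5.5, 10), `ddc_step`.
#'
#' @param config A named list or the path to a YAML file.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the `ff_calibration` object, the
#'   consistency metrics, the point-test results and the output paths.
#' @export
run_calibration <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  require_fields(config, c("out_dir", "inputs"), "run_calibration")
  species <- config$species %||% "Anthocharis cardamines"
  assumptions <- config$assumptions %||% c("sva", "oba")
  t0_values <- config$t0_values %||% c(0, 5.5, 10)
  ddc_step <- config$ddc_step %||% 1

  sets <- purrr::map(config$inputs, read_input_set, species = species,
                     quiet = quiet)
  ff <- purrr::map(sets, function(s) {
    if (nrow(s$sightings) == 0) {
      ff_abort_data("A sightings input is empty after species filtering.")
    }
    ded <- dedupe_location_year(s$sightings)
    if (!quiet) {
      inform(sprintf(
        "Dedupe: %d sighting(s) -> %d location-year record(s).",
        nrow(s$sightings), nrow(ded)
      ))
    }
    purrr::map(assumptions, function(a) {
      build_ff_dataset(ded, s$regions, s$spec, assumption = a, quiet = quiet)
    }) |>
      purrr::list_rbind()
  }) |>
    purrr::list_rbind()
  if (nrow(ff) == 0) {
    ff_abort_data("No first-flight observations remain after filtering.")
  }

  dd_table <- purrr::map(sets, function(s) {
    cell_dd <- accumulate_dd(s$temps, t0_values, quiet = quiet)
    regional_average_dd(cell_dd, s$regions)
  }) |>
    purrr::list_rbind()

  fit <- calibrate_ff_model(ff, dd_table, ddc_step = ddc_step)
  cons <- if (all(table(fit$best$assumption) >= 2)) {
    consistency_metrics(fit$best)
  } else {
    NULL  # cross-regional spread is undefined with a single region
  }
  cell_dd_all <- purrr::map(
    sets, ~ accumulate_dd(.x$temps, t0_values, quiet = TRUE)
  ) |>
    purrr::list_rbind()
  pt <- point_test(ff, cell_dd_all, fit$best, quiet = quiet)

  out_dir <- ensure_out_dir(config$out_dir, quiet = quiet)
  paths <- list(
    report = file.path(out_dir, "calibration_report.json"),
    curves = file.path(out_dir, "rmse_curves.csv"),
    regional_dd = file.path(out_dir, "regional_dd.csv"),
    ff = file.path(out_dir, "ff_dataset.csv")
  )
  jsonlite::write_json(
    list(
      best = fit$best, minima = fit$minima, consistency = cons,
      point_test = pt, observed_regional_ff = fit$observed,
      settings = fit$settings
    ),
    paths$report, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  readr::write_csv(fit$curves, paths$curves, progress = FALSE)
  write_regional_dd(dd_table, paths$regional_dd)
  write_ff_dataset(ff, paths$ff)
  write_manifest(out_dir, config)
  invisible(list(
    fit = fit, consistency = cons, point_test = pt, dd_table = dd_table,
    ff = ff, paths = paths
  ))
}

#' Run the two-period change assessment
#'
#' Computes period mean modeled first-flight dates, their advancement,
#' regional mean temperature change and fixed-window degree-day changes
#' between two climate periods, and writes them as CSV plus a manifest.
#'
#' Config fields: `out_dir`; `periods`: `list(p1 = c(start, end), p2 =
#' c(start, end))`; models either explicit (`models`: list of lists with
#' `assumption`, `region`, `t0`, `dd_c`) or from a calibration report
#' (`calibration_report` path); `regional_dd` path (or `inputs` as in
#' [run_calibration()] to recompute it); optional `dd_windows`.
#'
#' @param config A named list or the path to a YAML file.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the change table, the degree-day change
#'   table and the output paths.
#' @export
run_change <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  require_fields(config, c("out_dir", "periods"), "run_change")
  p1 <- as.integer(unlist(config$periods$p1))
  p2 <- as.integer(unlist(config$periods$p2))

  models <- if (!is.null(config$models)) {
    purrr::map(config$models, as_tibble) |> purrr::list_rbind()
  } else if (!is.null(config$calibration_report)) {
    rep <- jsonlite::fromJSON(config$calibration_report)
    as_tibble(rep$best)
  } else {
    ff_abort_config("Config for run_change needs `models` or `calibration_report`.")
  }

  temps <- NULL
  regions <- NULL
  if (!is.null(config$regional_dd)) {
    dd_table <- read_regional_dd(config$regional_dd)
  } else if (!is.null(config$inputs)) {
    t0_values <- sort(unique(c(models$t0, config$t0_values %||% numeric(0))))
    sets <- purrr::map(config$inputs, read_input_set,
                       species = config$species %||% NULL, quiet = quiet)
    dd_table <- purrr::map(sets, function(s) {
      regional_average_dd(accumulate_dd(s$temps, t0_values, quiet = quiet),
                          s$regions)
    }) |>
      purrr::list_rbind()
    temps <- purrr::map(sets, "temps") |> purrr::list_rbind()
    regions <- purrr::map(sets, "regions") |> purrr::list_rbind()
  } else {
    ff_abort_config("Config for run_change needs `regional_dd` or `inputs`.")
  }

  covered <- range(dd_table$year)
  if (min(p1, p2) < covered[1] || max(p1, p2) > covered[2]) {
    ff_abort_data("Requested periods fall outside the temperature coverage.")
  }

  change <- assess_change(dd_table, models, p1, p2, temps = temps,
                          regions = regions, quiet = quiet)
  ddch <- period_dd_change(dd_table, p1, p2,
                           windows = config$dd_windows %||% c("07-31", "annual"))

  out_dir <- ensure_out_dir(config$out_dir, quiet = quiet)
  paths <- list(
    change = file.path(out_dir, "change_assessment.csv"),
    dd_change = file.path(out_dir, "dd_change.csv"),
    json = file.path(out_dir, "change_report.json")
  )
  readr::write_csv(change, paths$change, progress = FALSE)
  readr::write_csv(ddch, paths$dd_change, progress = FALSE)
  jsonlite::write_json(
    list(periods = list(p1 = p1, p2 = p2), change = change, dd_change = ddch),
    paths$json, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  write_manifest(out_dir, config)
  invisible(list(change = change, dd_change = ddch, paths = paths))
}
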