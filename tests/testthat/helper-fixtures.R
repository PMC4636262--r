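# Shared builders for synthetic fixtures; everything is generated in code.

# constant-temperature grid over whole calendar years
make_const_temps <- function(tmax, tmin, years = 2001,
                             spec = grid_spec(10, 55, 1, 1), cells = NULL) {
  cc <- cell_centers(spec)
  if (!is.null(cells)) {
    cc <- dplyr::semi_join(cc, cells, by = c("lon_index", "lat_index"))
  }
  dates <- as.Date(unlist(lapply(
    sort(years),
    function(y) seq(as.Date(sprintf("%d-01-01", y)),
                    as.Date(sprintf("%d-12-31", y)), 1)
  )), origin = "1970-01-01")
  out <- tidyr::expand_grid(
    cc[, c("lon_index", "lat_index")],
    tibble::tibble(date = dates)
  )
  out$tmax <- tmax
  out$tmin <- tmin
  attr(out, "grid_spec") <- spec
  out
}

all_cells_region <- function(spec, name = "R") {
  cc <- cell_centers(spec)
  tibble::tibble(region = name, lon_index = cc$lon_index,
                 lat_index = cc$lat_index)
}

# build an FF tibble directly from cell/year/day triples
make_ff <- function(days_by_cell_year, assumption = "sva", region = "R") {
  # days_by_cell_year: data frame lon_index, lat_index, year, day_of_year
  df <- tibble::as_tibble(days_by_cell_year)
  df$assumption <- assumption
  df$region <- region
  if (!"lon" %in% names(df)) df$lon <- 10 + df$lon_index * 0.25 + 0.1
  if (!"lat" %in% names(df)) df$lat <- 55 + df$lat_index * 0.25 + 0.1
  df[, c("assumption", "region", "lon_index", "lat_index", "year",
         "day_of_year", "lon", "lat")]
}

# independent slow oracle for daily degree-days (scalar, literal branches)
oracle_delta_dd <- function(tmax, tmin, t0) {
  tmean <- 0.5 * (tmax + tmin)
  if (tmax <= t0) return(0)
  if (tmin >= t0) return(tmean - t0)
  if (tmean >= t0 && tmin < t0) return(0.5 * (tmax - t0) - 0.25 * (t0 - tmin))
  0.25 * (tmax - t0)
}
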