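#' Define a regular longitude-latitude grid
#'
#' A `grid_spec` describes the regular grid that gridded daily temperatures
#' live on: the lower-left (south-west) corner of the first cell, the cell
#' size in degrees, and the number of cells in each direction. The default
#' cell size of 0.25 degrees matches common blended gridded-temperature
#' products for Europe.
#'
#' Cell indices are 0-based. Each cell is half-open in both coordinates:
#' cell `i` spans `[origin + i * cell_size, origin + (i + 1) * cell_size)`,
#' so a point exactly on the shared boundary of two cells belongs to the
#' cell on its east/north side, and a point on the grid's outer maximum
#' edge is outside the grid.
#'
#' @param origin_lon,origin_lat Longitude/latitude of the grid origin
#'   (south-west corner of cell (0, 0)), decimal degrees.
#' @param n_lon,n_lat Number of cells along longitude/latitude; at least 1.
#' @param cell_size Cell edge length in degrees; must be positive.
#'
#' @return An object of class `grid_spec`.
#' @examples
#' spec <- grid_spec(10, 55, n_lon = 4, n_lat = 4)
#' cell_centers(spec)
#' @export
grid_spec <- function(origin_lon, origin_lat, n_lon, n_lat, cell_size = 0.25) {
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    ff_abort_format("`cell_size` must be a single positive number.")
  }
  n_lon <- as.integer(n_lon)
  n_lat <- as.integer(n_lat)
  if (is.na(n_lon) || n_lon < 1 || is.na(n_lat) || n_lat < 1) {
    ff_abort_format("`n_lon` and `n_lat` must be integers >= 1.")
  }
  if (!is.finite(origin_lon) || !is.finite(origin_lat)) {
    ff_abort_format("Grid origin coordinates must be finite.")
  }
  structure(
    list(
      origin_lon = as.numeric(origin_lon), origin_lat = as.numeric(origin_lat),
      cell_size = as.numeric(cell_size), n_lon = n_lon, n_lat = n_lat
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells of %.3g deg, origin (%.4g, %.4g)\n",
    x$n_lon, x$n_lat, x$cell_size, x$origin_lon, x$origin_lat
  ))
  invisible(x)
}

#' Cell centers of a grid
#'
#' @param spec A [grid_spec()].
#' @return A tibble with one row per cell: `lon_index`, `lat_index`
#'   (0-based) and the cell-center coordinates `lon`, `lat`.
#' @export
cell_centers <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  grid <- tidyr::expand_grid(
    lon_index = seq_len(spec$n_lon) - 1L,
    lat_index = seq_len(spec$n_lat) - 1L
  )
  grid |>
    mutate(
      lon = spec$origin_lon + (lon_index + 0.5) * spec$cell_size,
      lat = spec$origin_lat + (lat_index + 0.5) * spec$cell_size
    )
}

#' Assign point locations to grid cells
#'
#' Maps each (lon, lat) point in `data` to the grid cell containing it under
#' the half-open convention of [grid_spec()]. Points outside the grid extent
#' (including points exactly on the outer maximum edge) get `NA` indices.
#'
#' @param data A data frame with numeric `lon` and `lat` columns.
#' @param spec A [grid_spec()].
#' @return `data` with integer columns `lon_index` and `lat_index` appended.
#' @examples
#' spec <- grid_spec(10, 55, 2, 2)
#' assign_cell(tibble::tibble(lon = c(10.1, 10.25, 9.0), lat = 55.1), spec)
#' @export
assign_cell <- function(data, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  if (!all(c("lon", "lat") %in% names(data))) {
    ff_abort_format("`data` must have `lon` and `lat` columns.")
  }
  li <- floor((data$lon - spec$origin_lon) / spec$cell_size)
  la <- floor((data$lat - spec$origin_lat) / spec$cell_size)
  ok <- li >= 0 & li < spec$n_lon & la >= 0 & la < spec$n_lat &
    is.finite(li) & is.finite(la)
  data$lon_index <- ifelse(ok, as.integer(li), NA_integer_)
  data$lat_index <- ifelse(ok, as.integer(la), NA_integer_)
  data
}

## regions -------------------------------------------------------------------

#' Read and write region definitions
#'
#' Regions group grid cells for regional averaging. The on-disk format is a
#' JSON object mapping each region name to a list of `[lon_index, lat_index]`
#' pairs (0-based).
#'
#' @param path File path.
#' @param regions A tibble with columns `region`, `lon_index`, `lat_index`.
#' @param spec Optional [grid_spec()]; when supplied, membership is checked
#'   against the grid bounds.
#' @return `read_regions_json()` returns the regions tibble;
#'   `write_regions_json()` returns `path` invisibly.
#' @export
read_regions_json <- function(path, spec = NULL) {
  raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (length(raw) == 0) ff_abort_format("Region file defines no regions.")
  out <- purrr::imap(raw, function(cells, name) {
    m <- matrix(as.integer(unlist(cells)), ncol = 2, byrow = !is.matrix(cells))
    if (is.matrix(cells)) m <- matrix(as.integer(cells), ncol = 2)
    tibble(region = name, lon_index = m[, 1], lat_index = m[, 2])
  }) |>
    purrr::list_rbind()
  validate_regions(out, spec)
}

#' @rdname read_regions_json
#' @export
write_regions_json <- function(regions, path) {
  validate_regions(regions)
  lst <- purrr::map(
    split(regions, regions$region),
    ~ unname(purrr::map2(.x$lon_index, .x$lat_index, c))
  )
  jsonlite::write_json(lst, path, auto_unbox = FALSE)
  invisible(path)
}

validate_regions <- function(regions, spec = NULL) {
  need <- c("region", "lon_index", "lat_index")
  if (!all(need %in% names(regions))) {
    ff_abort_format("Regions need columns region, lon_index, lat_index.")
  }
  if (nrow(regions) == 0) ff_abort_format("Regions must be non-empty.")
  if (!is.null(spec)) {
    bad <- regions$lon_index < 0 | regions$lon_index >= spec$n_lon |
      regions$lat_index < 0 | regions$lat_index >= spec$n_lat
    if (any(bad)) {
      ff_abort_format(sprintf(
        "%d region cell(s) fall outside the grid bounds.", sum(bad)
      ))
    }
  }
  as_tibble(regions)
}
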