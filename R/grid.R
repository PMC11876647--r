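#' Regular lat/lon grid specification
#'
#' Cell-center registered regular grid. Latitude centers are stored
#' descending (+90 to -90) and longitude centers ascending (-180 to 180),
#' matching common 0.05-degree climate-grid products; area weights for
#' spatial aggregation are then simply `cos(lat_center)`.
#'
#' @param nlat,nlon number of rows / columns.
#' @param cell_size cell size in degrees (default 0.05).
#' @param lat0,lon0 northern / western outer edge of the grid (degrees).
#'   Defaults place a small grid at a mid-latitude test domain.
#' @return a `grid_spec` object with `lat`, `lon` (cell centers, degrees)
#'   and `cell_size`.
#' @examples
#' g <- grid_spec(4, 4, cell_size = 0.05)
#' diff(g$lon)
#' @export
grid_spec <- function(nlat, nlon, cell_size = 0.05, lat0 = 45, lon0 = 0) {
  check_that(nlat >= 1 && nlon >= 1, "grid must have at least one cell")
  check_that(cell_size > 0, "cell_size must be positive")
  lat <- lat0 - cell_size / 2 - cell_size * (seq_len(nlat) - 1L)
  lon <- lon0 + cell_size / 2 + cell_size * (seq_len(nlon) - 1L)
  structure(list(lat = lat, lon = lon, cell_size = cell_size),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.4g deg, lat %.3f..%.3f, lon %.3f..%.3f\n",
              length(x$lat), length(x$lon), x$cell_size,
              max(x$lat), min(x$lat), min(x$lon), max(x$lon)))
  invisible(x)
}

grid_dim <- function(grid) c(length(grid$lat), length(grid$lon))

# build a grid_spec from coordinate vectors, normalizing orientation.
# Returns list(grid, flip_lat, flip_lon) so callers can reorder data.
grid_from_coords <- function(lat, lon) {
  dl <- diff(lat); dn <- diff(lon)
  if (length(dl) > 0 && !(all(dl > 0) || all(dl < 0)))
    abort("latitude axis is not monotonic", class = "lcspp_format_error")
  if (length(dn) > 0 && !(all(dn > 0) || all(dn < 0)))
    abort("longitude axis is not monotonic", class = "lcspp_format_error")
  flip_lat <- length(dl) > 0 && all(dl > 0)   # ascending -> flip to descending
  flip_lon <- length(dn) > 0 && all(dn < 0)
  if (flip_lat) lat <- rev(lat)
  if (flip_lon) lon <- rev(lon)
  step <- if (length(lat) > 1) abs(lat[1] - lat[2]) else
    if (length(lon) > 1) abs(lon[2] - lon[1]) else 0.05
  g <- structure(list(lat = lat, lon = lon, cell_size = step),
                 class = "grid_spec")
  list(grid = g, flip_lat = flip_lat, flip_lon = flip_lon)
}
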