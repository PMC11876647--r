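#' Gridded data cubes
#'
#' All gridded records in the package share one container: a list holding a
#' [grid_spec()], a biweekly (or daily) time table, and data arrays with
#' dimensions `lat x lon x time` (float64 in memory, float32 on disk;
#' missing cells are `NaN`). Three flavours exist:
#'
#' * `refl_cube` - red/NIR reflectance composites with per-composite solar
#'   zenith angle (`sza`, degrees), integer QC bitmask (`qc`) and per-step
#'   `sensor_id`.
#' * `met_cube` - meteorological covariates `ta` (deg C), `p` (mm/period),
#'   `rad` (W m-2), `aod`, `sd` (m), `cc` (0-1) plus static `ele` (m) and
#'   `ai` (aridity index) layers.
#' * `lcspp_cube` - the three proxy layers `clear_inst`, `clear_daily`,
#'   `all_daily` (mW m-2 nm-1 sr-1) with their geometry/radiation terms.
#'
#' @param grid a [grid_spec()].
#' @param time a time table as returned by [biweekly_seq()].
#' @param ... named arrays (`lat x lon x time`), static matrices
#'   (`lat x lon`) or per-time vectors (e.g. `sensor_id`).
#' @param class cube subclass.
#' @return an object of class `c(class, "lcspp_cube")`.
#' @export
new_cube <- function(grid, time, ..., class = "refl_cube") {
  fields <- list(...)
  nt <- nrow(time)
  nd <- grid_dim(grid)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (is.array(f) && length(dim(f)) == 3L)
      check_that(all(dim(f) == c(nd, nt)),
                 "field '", nm, "' does not match grid/time dimensions")
  }
  structure(c(list(grid = grid, time = time), fields),
            class = c(class, "lcspp_cube"))
}

cube_fields <- function(cube) setdiff(names(cube), c("grid", "time", "truth"))

#' @export
print.lcspp_cube <- function(x, ...) {
  nd <- grid_dim(x$grid)
  cat(sprintf("<%s> %d x %d pixels, %d time steps; fields: %s\n",
              class(x)[1], nd[1], nd[2], nrow(x$time),
              paste(cube_fields(x), collapse = ", ")))
  invisible(x)
}

#' Convert a cube to a long tibble
#'
#' One row per (pixel, time step) with the cube's array fields as columns;
#' handy for dplyr/ggplot2 work on small scenes.
#'
#' @param x a cube.
#' @param ... unused.
#' @return a tibble with `lat`, `lon`, time columns and one column per field.
#' @method as_tibble lcspp_cube
#' @export
as_tibble.lcspp_cube <- function(x, ...) {
  nd <- grid_dim(x$grid)
  nt <- nrow(x$time)
  base <- tidyr::expand_grid(index = x$time$index %||% seq_len(nt),
                             lon = x$grid$lon, lat = x$grid$lat)
  base <- dplyr::arrange(base, .data$index)
  out <- dplyr::left_join(base, x$time, by = "index")
  for (nm in cube_fields(x)) {
    f <- x[[nm]]
    if (is.array(f) && length(dim(f)) == 3L) out[[nm]] <- as.vector(f)
    else if (is.matrix(f)) out[[nm]] <- rep(as.vector(f), nt)
    else if (length(f) == nt) out[[nm]] <- rep(f, each = prod(nd))
  }
  tibble::as_tibble(out)
}

sensor_chr_width <- 16L

cube_nc_vars <- function(cube) {
  nd <- grid_dim(cube$grid)
  nt <- nrow(cube$time)
  vars <- list(
    list(name = "lat", dims = "lat", type = "double", data = cube$grid$lat,
         atts = list(units = "degrees_north")),
    list(name = "lon", dims = "lon", type = "double", data = cube$grid$lon,
         atts = list(units = "degrees_east")),
    list(name = "time", dims = "time", type = "int",
         data = as.integer(cube$time$mid_date),
         atts = list(units = "days since 1970-01-01", calendar = "standard")))
  for (nm in cube_fields(cube)) {
    f <- cube[[nm]]
    if (is.character(f)) {
      padded <- formatC(f, width = sensor_chr_width, flag = "-")
      vars[[length(vars) + 1L]] <- list(
        name = nm, dims = c("time", "strlen"), type = "char",
        data = paste(substr(padded, 1, sensor_chr_width), collapse = ""))
    } else if (is.array(f) && length(dim(f)) == 3L) {
      type <- if (nm == "qc") "int" else "float"
      d <- aperm(f, c(2, 1, 3))  # -> lon, lat, time (lon fastest on disk)
      atts <- if (type == "float") list(`_FillValue` = NaN) else list()
      vars[[length(vars) + 1L]] <- list(name = nm, dims = c("time", "lat", "lon"),
                                        type = type,
                                        data = if (type == "int") {
                                          di <- as.integer(d); dim(di) <- dim(d); di
                                        } else d,
                                        atts = atts)
    } else if (is.matrix(f)) {
      vars[[length(vars) + 1L]] <- list(name = nm, dims = c("lat", "lon"),
                                        type = "float", data = t(f),
                                        atts = list(`_FillValue` = NaN))
    } else if (is.numeric(f) && length(f) == nt) {
      vars[[length(vars) + 1L]] <- list(name = nm, dims = "time",
                                        type = "float", data = f)
    }
  }
  vars
}

#' Write a cube to a NetCDF file
#'
#' Data layers are stored as float32 with `_FillValue = NaN`; QC as int32;
#' `sensor_id` as a fixed-width char array. The cube subclass is recorded in
#' a global attribute so [read_cube()] can restore it.
#'
#' @param cube a cube object.
#' @param path output `.nc` path.
#' @return `path` invisibly.
#' @export
write_cube <- function(cube, path) {
  nd <- grid_dim(cube$grid)
  dims <- c(lat = nd[1], lon = nd[2], time = nrow(cube$time),
            strlen = sensor_chr_width)
  nc3_write(path, dims, cube_nc_vars(cube),
            gatts = list(Conventions = "CF-1.6",
                         lcspp_cube_class = class(cube)[1]))
  invisible(path)
}

#' Read a cube from a NetCDF file
#'
#' CF-style `lat`/`lon`/`time` coordinates are required; an ascending
#' latitude axis is reordered to the package's descending convention with
#' the data flipped consistently.
#'
#' @param path a `.nc` file written by [write_cube()] (or any classic
#'   NetCDF file following the same layout).
#' @param variables optional character vector restricting which data
#'   variables to load; an absent name is an error listing what is present.
#' @return a cube object.
#' @export
read_cube <- function(path, variables = NULL) {
  check_that(file.exists(path), "file not found: ", path)
  nc <- nc3_read(path)
  for (ax in c("lat", "lon", "time"))
    if (is.null(nc$vars[[ax]]))
      abort(sprintf("malformed coordinates: missing axis '%s'", ax),
            class = "lcspp_format_error")
  cf <- grid_from_coords(as.numeric(nc$vars$lat$data),
                         as.numeric(nc$vars$lon$data))
  mid_date <- as.Date(as.numeric(nc$vars$time$data), origin = "1970-01-01")
  time <- biweekly_index_of(mid_date)
  time$index <- seq_len(nrow(time))
  time$mid_date <- mid_date

  data_names <- setdiff(names(nc$vars), c("lat", "lon", "time"))
  if (!is.null(variables)) {
    missing <- setdiff(variables, data_names)
    if (length(missing) > 0)
      abort(sprintf("variable(s) %s not in file; available: %s",
                    paste(missing, collapse = ", "),
                    paste(data_names, collapse = ", ")),
            class = "lcspp_format_error")
    data_names <- variables
  }
  fields <- list()
  for (nm in data_names) {
    v <- nc$vars[[nm]]
    if (v$type == "char") {
      n <- nchar(v$data) %/% sensor_chr_width
      fields[[nm]] <- trimws(substring(v$data,
                                       (seq_len(n) - 1) * sensor_chr_width + 1,
                                       seq_len(n) * sensor_chr_width))
    } else if (length(v$dims) == 3L) {
      a <- aperm(v$data, c(2, 1, 3))  # lon,lat,time -> lat,lon,time
      if (cf$flip_lat) a <- a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
      if (cf$flip_lon) a <- a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
      storage.mode(a) <- if (nm == "qc") "integer" else "double"
      fields[[nm]] <- a
    } else if (length(v$dims) == 2L) {
      a <- t(v$data)
      if (cf$flip_lat) a <- a[rev(seq_len(nrow(a))), , drop = FALSE]
      if (cf$flip_lon) a <- a[, rev(seq_len(ncol(a))), drop = FALSE]
      fields[[nm]] <- a
    } else {
      fields[[nm]] <- as.numeric(v$data)
    }
  }
  cls <- nc$gatts$lcspp_cube_class %||% "refl_cube"
  do.call(new_cube, c(list(grid = cf$grid, time = time), fields,
                      list(class = cls)))
}

#' Write a product cube as one file per biweekly period
#'
#' Files are named `<prefix>_<YYYYMM><a|b>.nc`, two per complete month;
#' partial months at record edges are written with the periods present.
#'
#' @param cube a cube on a biweekly time axis.
#' @param directory output directory (created if needed).
#' @param prefix file name prefix.
#' @param overwrite set `TRUE` to allow writing into a directory that
#'   already contains files with the same prefix.
#' @return character vector of the files written.
#' @export
write_product <- function(cube, directory, prefix = "LCSPP", overwrite = FALSE) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  labels <- period_label(cube$time)
  paths <- file.path(directory, sprintf("%s_%s.nc", prefix, labels))
  clash <- file.exists(paths)
  if (any(clash) && !overwrite)
    abort(paste0("refusing to overwrite existing files (e.g. ",
                 basename(paths[clash][1]), "); pass overwrite = TRUE"),
          class = "lcspp_io_error")
  for (k in seq_len(nrow(cube$time))) {
    slice_fields <- list()
    for (nm in cube_fields(cube)) {
      f <- cube[[nm]]
      if (is.array(f) && length(dim(f)) == 3L)
        slice_fields[[nm]] <- f[, , k, drop = FALSE]
      else if (is.matrix(f)) slice_fields[[nm]] <- f
      else if (length(f) == nrow(cube$time)) slice_fields[[nm]] <- f[k]
    }
    slice <- do.call(new_cube, c(list(grid = cube$grid,
                                      time = cube$time[k, , drop = FALSE]),
                                 slice_fields, list(class = class(cube)[1])))
    write_cube(slice, paths[k])
  }
  paths
}
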