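# QC bitmask convention shared by the generator and the filters.
# A cell is usable iff none of the requested bits are set.
qc_bits <- c(cloud = 1L, snow = 2L, night = 4L, water = 8L,
             polar = 16L, brdf_bad = 32L, band_invalid = 64L)

#' RossThick volumetric scattering kernel
#'
#' @param sza,vza,raa solar zenith, view zenith and relative azimuth angles
#'   in degrees; `sza`/`vza` must be below 90.
#' @return kernel value (unitless).
#' @export
kernel_ross_thick <- function(sza, vza, raa) {
  check_that(all(sza >= 0 & sza < 90) && all(vza >= 0 & vza < 90),
             "sza and vza must be in [0, 90)")
  ts <- sza * pi / 180; tv <- vza * pi / 180; phi <- raa * pi / 180
  cosxi <- cos(ts) * cos(tv) + sin(ts) * sin(tv) * cos(phi)
  cosxi <- pmin(pmax(cosxi, -1), 1)
  xi <- acos(cosxi)
  ((pi / 2 - xi) * cos(xi) + sin(xi)) / (cos(ts) + cos(tv)) - pi / 4
}

#' LiSparse-Reciprocal geometric scattering kernel
#'
#' Operational constants `h/b = 2`, `b/r = 1`.
#'
#' @inheritParams kernel_ross_thick
#' @return kernel value (unitless).
#' @export
kernel_li_sparse_r <- function(sza, vza, raa) {
  check_that(all(sza >= 0 & sza < 90) && all(vza >= 0 & vza < 90),
             "sza and vza must be in [0, 90)")
  hb <- 2; br <- 1
  ts <- atan(br * tan(sza * pi / 180))
  tv <- atan(br * tan(vza * pi / 180))
  phi <- raa * pi / 180
  cosxi <- cos(ts) * cos(tv) + sin(ts) * sin(tv) * cos(phi)
  cosxi <- pmin(pmax(cosxi, -1), 1)
  d2 <- tan(ts)^2 + tan(tv)^2 - 2 * tan(ts) * tan(tv) * cos(phi)
  sec_sum <- 1 / cos(ts) + 1 / cos(tv)
  cost <- hb * sqrt(pmax(d2, 0) + (tan(ts) * tan(tv) * sin(phi))^2) / sec_sum
  cost <- pmin(pmax(cost, -1), 1)
  t <- acos(cost)
  overlap <- (1 / pi) * (t - sin(t) * cos(t)) * sec_sum
  overlap - sec_sum + 0.5 * (1 + cosxi) / (cos(ts) * cos(tv))
}

#' Kernel-driven surface reflectance at a given geometry
#'
#' Evaluates the RossThick-LiSparseReciprocal kernel model,
#' `rho = f_iso + f_vol * K_RossThick + f_geo * K_LiSparseR`, the standard
#' way BRDF model-parameter products are converted to reflectance at a
#' standard geometry (45 deg solar zenith, nadir view, 0 relative azimuth
#' by default).
#'
#' @param f_iso,f_vol,f_geo kernel weights (vectors or arrays).
#' @param sza,vza,raa observation geometry, degrees.
#' @return reflectance with the shape of the weights.
#' @export
brdf_reflectance <- function(f_iso, f_vol, f_geo, sza = 45, vza = 0, raa = 0) {
  f_iso + f_vol * kernel_ross_thick(sza, vza, raa) +
    f_geo * kernel_li_sparse_r(sza, vza, raa)
}

#' Mask observations failing QC bits
#'
#' Cells with any of the requested bits set in the `qc` layer have their
#' `red`, `nir` and `sza` values replaced by `NaN`. Removal counts per
#' reason are attached as the `"removal_counts"` attribute.
#'
#' @param cube a daily scene or biweekly `refl_cube` with a `qc` field.
#' @param policy character vector of bit names to enforce; defaults to all
#'   of `cloud`, `snow`, `night`, `water`, `polar`, `brdf_bad`,
#'   `band_invalid`.
#' @return the masked cube.
#' @export
qc_filter <- function(cube, policy = names(qc_bits)) {
  unknown <- setdiff(policy, names(qc_bits))
  if (length(unknown) > 0)
    abort(paste0("unknown QC bit name(s): ", paste(unknown, collapse = ", "),
                 "; known: ", paste(names(qc_bits), collapse = ", ")),
          class = "lcspp_config_error")
  counts <- integer(0)
  bad <- array(FALSE, dim(cube$qc))
  for (nm in policy) {
    hit <- bitwAnd(cube$qc, qc_bits[[nm]]) != 0L
    counts[nm] <- sum(hit)
    bad <- bad | hit
  }
  for (f in intersect(c("red", "nir", "sza"), names(cube)))
    cube[[f]][bad] <- NaN
  attr(cube, "removal_counts") <- counts
  cube
}

#' Mask all observations inside exclusion windows
#'
#' Periods with known instrumental malfunctions or anomalous observations
#' are removed from the record regardless of QC; overlapping windows are
#' treated as their union.
#'
#' @param cube a daily scene (with `date`) or biweekly cube (with `time`).
#' @param windows a list of length-2 date vectors `c(start, end)`
#'   (inclusive), or a data frame with `start`/`end` columns.
#' @return the cube with excluded steps masked to `NaN`.
#' @export
apply_exclusion_windows <- function(cube, windows) {
  if (is.data.frame(windows))
    windows <- purrr::map2(windows$start, windows$end, c)
  if (length(windows) == 0) return(cube)
  when <- if (!is.null(cube$date)) as.Date(cube$date) else cube$time$mid_date
  hit <- rep(FALSE, length(when))
  for (w in windows) {
    w <- as.Date(w)
    check_that(length(w) == 2 && !any(is.na(w)), "invalid exclusion window")
    hit <- hit | (when >= min(w) & when <= max(w))
  }
  for (f in intersect(c("red", "nir", "sza"), names(cube)))
    cube[[f]][, , hit] <- NaN
  attr(cube, "excluded_steps") <- which(hit)
  cube
}

#' Maximum-value compositing of daily observations to biweekly periods
#'
#' For each pixel and biweekly period the valid day maximizing
#' `NDVI = (nir - red)/(nir + red)` is selected and its red, NIR, solar
#' zenith angle and sensor id are carried into the composite (the band
#' *pair* is kept coherent). Ties are broken by the earliest day; days with
#' `nir + red = 0` are treated as invalid. Periods with no valid day are
#' missing.
#'
#' @param daily a daily scene (as produced by [simulate_scene()] with
#'   `cadence = "daily"`): arrays `red`, `nir`, `sza` of dim
#'   lat x lon x n_days, a `date` vector and per-day `sensor_id`.
#' @return a biweekly `refl_cube`.
#' @export
composite_mvc <- function(daily) {
  check_that(!is.null(daily$date), "daily scene must carry a 'date' vector")
  nd <- grid_dim(daily$grid)
  idx <- biweekly_index_of(daily$date)
  years <- range(idx$year)
  time <- biweekly_seq(years[1], years[2])
  key <- paste(idx$year, idx$ordinal)
  tkey <- paste(time$year, time$ordinal)
  keep <- tkey %in% key
  time <- time[keep, , drop = FALSE]
  time$index <- seq_len(nrow(time))
  tkey <- tkey[keep]
  nt <- nrow(time)

  denom <- daily$nir + daily$red
  ndvi <- (daily$nir - daily$red) / denom
  ndvi[!is.finite(ndvi) | denom == 0] <- NaN

  red <- nir <- sza <- array(NaN, c(nd, nt))
  qc <- array(qc_bits[["band_invalid"]], c(nd, nt))
  sensor <- rep(NA_character_, nt)
  for (k in seq_len(nt)) {
    days <- which(key == tkey[k])
    nv <- ndvi[, , days, drop = FALSE]
    valid <- is.finite(nv)
    any_valid <- apply(valid, c(1, 2), any)
    # which.max returns the first maximum: with days in chronological order
    # this is the documented earliest-day tie rule.
    nv[!valid] <- -Inf
    best <- apply(nv, c(1, 2), which.max)
    pick <- cbind(as.vector(row(best)), as.vector(col(best)),
                  days[as.vector(best)])
    r <- daily$red[pick]; n <- daily$nir[pick]; s <- daily$sza[pick]
    ok <- as.vector(any_valid)
    red[, , k][ok] <- r[ok]
    nir[, , k][ok] <- n[ok]
    sza[, , k][ok] <- s[ok]
    qc[, , k][ok] <- 0L
    # composite sensor id: the sensor observing this period (epochs do not
    # straddle a biweekly period in practice; take the modal day's sensor)
    sensor[k] <- daily$sensor_id[days[1]]
  }
  new_cube(daily$grid, time, red = red, nir = nir, sza = sza, qc = qc,
           sensor_id = sensor, class = "refl_cube")
}
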