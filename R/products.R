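#' Solar geometry
#'
#' Cosine of the solar zenith angle from latitude, day of year and local
#' solar time, using the Spencer truncated-Fourier series for the solar
#' declination. The value may be negative (sun below the horizon).
#'
#' @param lat latitude, degrees.
#' @param doy day of year (1-366).
#' @param local_solar_time local solar hours (decimal); 12 is solar noon.
#' @return cosine of the solar zenith angle (vectorized over inputs).
#' @examples
#' cos_sza(0, 80, 12)          # near-overhead sun at the equinox
#' cos_sza(90, 355, 12) < 0    # polar night
#' @export
cos_sza <- function(lat, doy, local_solar_time = 13.6) {
  decl <- solar_declination(doy)
  h <- (local_solar_time - 12) * 15 * pi / 180   # hour angle
  latr <- lat * pi / 180
  sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(h)
}

# Spencer (1971) series; returns declination in radians
solar_declination <- function(doy) {
  g <- 2 * pi * (doy - 1) / 365
  0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
}

# Spencer eccentricity correction factor E0 = (r0/r)^2
solar_eccentricity <- function(doy) {
  g <- 2 * pi * (doy - 1) / 365
  1.000110 + 0.034221 * cos(g) + 0.001280 * sin(g) +
    0.000719 * cos(2 * g) + 0.000077 * sin(2 * g)
}

#' 24-hour mean of the positive part of cos(SZA)
#'
#' Numerically integrates `max(cos(SZA(t)), 0)` over the day at a fixed
#' time step; exactly 0 in polar night.
#'
#' @inheritParams cos_sza
#' @param step_minutes integration step (must divide 24 h; default 2).
#' @return daily mean cosine, in `[0, 1]`.
#' @examples
#' daily_mean_cos_sza(0, 80)   # ~ 1/pi at the equator/equinox
#' @export
daily_mean_cos_sza <- function(lat, doy, step_minutes = 2) {
  check_that((24 * 60) %% step_minutes == 0,
             "step_minutes must divide 24 hours")
  hours <- seq(step_minutes / 120, 24 - step_minutes / 120,
               by = step_minutes / 60)
  n <- max(length(lat), length(doy))
  lat <- rep_len(lat, n); doy <- rep_len(doy, n)
  vapply(seq_len(n), function(i) {
    mean(pmax(cos_sza(lat[i], doy[i], hours), 0))
  }, numeric(1))
}

#' Clear-sky instantaneous photosynthetically active radiation
#'
#' A simple broadband clear-sky model: top-of-atmosphere irradiance scaled
#' by a bulk atmospheric transmittance raised to the relative air mass
#' (`1/cosSZA`), times a broadband-to-PAR fraction,
#' `PAR = S0 * E0(doy) * cosSZA * tau^(1/cosSZA) * f_par`.
#'
#' @param lat,doy latitude (degrees) and day of year.
#' @param local_solar_time local solar hours of the observation.
#' @param s0 solar constant, W m-2.
#' @param tau bulk atmospheric transmittance, (0, 1].
#' @param f_par broadband-to-PAR fraction, (0, 1).
#' @param eccentricity apply the sun-earth distance correction.
#' @return PAR in W m-2; 0 where the sun is below the horizon.
#' @export
clear_sky_par_inst <- function(lat, doy, local_solar_time = 13.6,
                               s0 = 1361, tau = 0.75, f_par = 0.45,
                               eccentricity = TRUE) {
  check_that(tau > 0 && tau <= 1, "tau must be in (0, 1]")
  check_that(f_par > 0 && f_par < 1, "f_par must be in (0, 1)")
  mu <- cos_sza(lat, doy, local_solar_time)
  e0 <- if (eccentricity) solar_eccentricity(doy) else 1
  out <- s0 * e0 * mu * tau^(1 / pmax(mu, 1e-12)) * f_par
  out[mu <= 0] <- 0
  out
}

#' Daily clear-sky layer from the instantaneous layer
#'
#' `clear_daily = clear_inst * cos_sza_daily / cos_sza_inst`; wherever
#' `cos_sza_inst <= 0` (polar winter at overpass) the output is 0.
#'
#' @param clear_inst instantaneous clear-sky proxy values.
#' @param cos_sza_inst cosine of SZA at the overpass time.
#' @param cos_sza_daily 24-h mean of `max(cosSZA, 0)`.
#' @return daily clear-sky values, same shape as `clear_inst`.
#' @export
clear_daily_from_inst <- function(clear_inst, cos_sza_inst, cos_sza_daily) {
  out <- clear_inst * cos_sza_daily / cos_sza_inst
  out[!is.finite(out) | cos_sza_inst <= 0] <- 0
  out
}

#' Daily all-sky layer from the instantaneous clear-sky layer
#'
#' `all_daily = clear_inst / par_clear_inst * par_daily`, scaling the
#' clear-sky proxy by the ratio of actual (cloud-affected) to clear-sky
#' radiation.
#'
#' @param clear_inst instantaneous clear-sky proxy.
#' @param par_clear_inst clear-sky instantaneous PAR (W m-2).
#' @param par_daily daily-mean all-sky downward radiation (W m-2).
#' @return all-sky daily values; 0 where `par_clear_inst` is 0 and
#'   `clear_inst` is 0, `NaN` (flagged inconsistency) where
#'   `par_clear_inst` is 0 but `clear_inst > 0`.
#' @export
all_daily_from_inst <- function(clear_inst, par_clear_inst, par_daily) {
  out <- clear_inst / par_clear_inst * par_daily
  zero <- par_clear_inst <= 0
  out[zero & clear_inst <= 0] <- 0
  bad <- zero & clear_inst > 0
  if (any(bad, na.rm = TRUE)) {
    warn(sprintf("%d cells have clear_inst > 0 with zero clear-sky PAR; set to NaN",
                 sum(bad, na.rm = TRUE)))
    out[bad] <- NaN
  }
  out
}

#' Reconstruct the three proxy product layers from a reflectance cube
#'
#' Runs the SIF emulator on a calibrated reflectance cube at the nominal
#' overpass geometry, then derives the daily clear-sky layer through the
#' daylight-mean solar zenith correction and the daily all-sky layer
#' through the clear-sky PAR ratio. Pixels with the overpass sun below the
#' horizon get 0 in all layers.
#'
#' @param cube a `refl_cube` with `red` and `nir` layers.
#' @param model an emulator fitted by [train_emulator()].
#' @param met optional `met_cube` supplying `rad` for the all-sky layer;
#'   without it only the clear-sky layers are produced.
#' @param overpass_lst nominal local solar overpass time, hours.
#' @param par_config list of clear-sky PAR parameters (`s0`, `tau`,
#'   `f_par`), see [clear_sky_par_inst()].
#' @return an `lcspp_cube` with layers `clear_inst`, `clear_daily`,
#'   `all_daily` (if `met` given) and the geometry/PAR terms.
#' @export
reconstruct_lcspp <- function(cube, model, met = NULL, overpass_lst = 13.6,
                              par_config = list(s0 = 1361, tau = 0.75,
                                                f_par = 0.45)) {
  nd <- grid_dim(cube$grid)
  nt <- nrow(cube$time)
  doy <- period_mid_doy(cube$time)

  mu_inst <- array(0, c(nd, nt))
  mu_daily <- array(0, c(nd, nt))
  par_inst <- array(0, c(nd, nt))
  for (k in seq_len(nt)) {
    mu_lat <- cos_sza(cube$grid$lat, doy[k], overpass_lst)
    mud_lat <- daily_mean_cos_sza(cube$grid$lat, doy[k])
    par_lat <- clear_sky_par_inst(cube$grid$lat, doy[k], overpass_lst,
                                  s0 = par_config$s0, tau = par_config$tau,
                                  f_par = par_config$f_par)
    mu_inst[, , k] <- matrix(mu_lat, nd[1], nd[2])
    mu_daily[, , k] <- matrix(mud_lat, nd[1], nd[2])
    par_inst[, , k] <- matrix(par_lat, nd[1], nd[2])
  }

  clear_inst <- predict_sif(model, as.vector(cube$red), as.vector(cube$nir),
                            as.vector(pmax(mu_inst, 0)))
  clear_inst[as.vector(mu_inst) <= 0] <- 0
  dim(clear_inst) <- c(nd, nt)
  clear_daily <- clear_daily_from_inst(clear_inst, mu_inst, mu_daily)

  fields <- list(clear_inst = clear_inst, clear_daily = clear_daily,
                 cos_sza_inst = mu_inst, cos_sza_daily = mu_daily,
                 par_clear_inst = par_inst)
  if (!is.null(met)) {
    fields$all_daily <- all_daily_from_inst(clear_inst, par_inst, met$rad)
    fields$par_daily <- met$rad
  }
  do.call(new_cube, c(list(grid = cube$grid, time = cube$time), fields,
                      list(class = "lcspp_product")))
}
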