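# Orbital-drift and inter-sensor bias removal.
#
# The drifting record's pixel-wise reflectance anomalies are regressed, for
# each of the 24 biweekly periods of the year, on the solar-zenith-angle
# anomaly, the global PICS-derived inter-sensor bias proxy and
# meteorological anomalies; only the SZA and bias-proxy contributions are
# then removed, retaining genuine weather-driven variability.

# per-pixel, per-period-of-year climatology (mean over years, NaN-aware)
clim_mean <- function(a, ordinal) {
  nd <- dim(a)[1:2]
  out <- array(NA_real_, c(nd, 24))
  for (p in 1:24) {
    k <- which(ordinal == p)
    if (length(k) == 0) next
    sl <- a[, , k, drop = FALSE]
    out[, , p] <- apply(sl, c(1, 2), function(v) {
      v <- v[is.finite(v)]
      if (length(v)) mean(v) else NA_real_
    })
  }
  out
}

clim_expand <- function(clim, ordinal) {
  out <- array(NA_real_, c(dim(clim)[1:2], length(ordinal)))
  for (k in seq_along(ordinal)) out[, , k] <- clim[, , ordinal[k]]
  out
}

# faster climatology via colMeans over reshaped matrix
clim_mean_fast <- function(a, ordinal) {
  nd <- dim(a)[1:2]; npix <- prod(nd)
  am <- matrix(a, npix, dim(a)[3])
  out <- array(NA_real_, c(nd, 24))
  for (p in 1:24) {
    k <- which(ordinal == p)
    if (length(k) == 0) next
    m <- am[, k, drop = FALSE]
    cnt <- rowSums(is.finite(m))
    s <- rowSums(m, na.rm = TRUE)
    v <- ifelse(cnt > 0, s / cnt, NA_real_)
    out[, , p] <- matrix(v, nd[1], nd[2])
  }
  out
}

cube_anomaly <- function(a, ordinal) {
  a - clim_expand(clim_mean_fast(a, ordinal), ordinal)
}

#' Inter-sensor bias proxy from pseudo-invariant calibration sites
#'
#' Averages the record over the calibration PICS pixels, builds the mean
#' seasonal cycle (MSC) of the reference-quality epoch per band and
#' period-of-year, and returns the per-composite deviation from that cycle,
#' `delta(t) = PICS_mean(t) - MSC_ref(period-of-year(t))`. Over drifting
#' epochs `delta` tracks the inter-sensor offset (plus any PICS-level drift
#' response); within the reference epoch it has mean ~0 by construction.
#'
#' @param cube a biweekly `refl_cube`.
#' @param pics_pixels linear pixel indices of the calibration PICS set.
#' @param epochs a [sensor_epoch_table()].
#' @return a `pics_bias` object: tibble `series` (`index`, `year`,
#'   `ordinal`, `delta_red`, `delta_nir`, `pics_red`, `pics_nir`) and
#'   tibble `msc` (`ordinal`, `msc_red`, `msc_nir`).
#' @export
compute_pics_bias <- function(cube, pics_pixels, epochs) {
  check_that(length(pics_pixels) > 0, "pics_pixels must be non-empty")
  iref <- which(epochs$reference)
  check_that(length(iref) == 1, "exactly one reference epoch required")
  nd <- grid_dim(cube$grid); npix <- prod(nd); nt <- nrow(cube$time)

  band_avg <- function(a) {
    m <- matrix(a, npix, nt)[pics_pixels, , drop = FALSE]
    colMeans(m, na.rm = TRUE)
  }
  pics_red <- band_avg(cube$red)
  pics_nir <- band_avg(cube$nir)

  in_ref <- cube$time$year >= epochs$start_year[iref] &
    cube$time$year <= epochs$end_year[iref]
  check_that(any(in_ref), "reference epoch not present in the record")
  msc <- tibble::tibble(ordinal = 1:24, msc_red = NA_real_, msc_nir = NA_real_)
  for (p in 1:24) {
    k <- which(in_ref & cube$time$ordinal == p & is.finite(pics_red))
    if (length(k) > 0) msc$msc_red[p] <- mean(pics_red[k])
    k <- which(in_ref & cube$time$ordinal == p & is.finite(pics_nir))
    if (length(k) > 0) msc$msc_nir[p] <- mean(pics_nir[k])
  }
  missing <- msc$ordinal[!is.finite(msc$msc_red) | !is.finite(msc$msc_nir)]
  if (length(missing) > 0)
    abort(paste0("mean seasonal cycle undefined for period-of-year: ",
                 paste(missing, collapse = ", "),
                 " (never observed in the reference epoch)"),
          class = "lcspp_data_error")

  series <- tibble::tibble(
    index = cube$time$index, year = cube$time$year,
    ordinal = cube$time$ordinal,
    pics_red = pics_red, pics_nir = pics_nir,
    delta_red = pics_red - msc$msc_red[cube$time$ordinal],
    delta_nir = pics_nir - msc$msc_nir[cube$time$ordinal])
  structure(list(series = series, msc = msc, pics_pixels = pics_pixels),
            class = "pics_bias")
}

#' Fit the per-pixel SZA/inter-sensor-bias anomaly regression
#'
#' For every pixel, band and period-of-year, ordinary least squares of the
#' reflectance anomaly on `[SZA anomaly, delta, Ta anomaly, P anomaly,
#' Rad anomaly, 1]`. Anomalies are taken relative to each pixel's own
#' period-of-year climatology over the record. The bias proxy `delta`
#' enters as the single global per-band series. Fits with fewer than
#' `min_n` usable years, or a rank-deficient design, are left unfitted and
#' flagged (`NA` coefficients; such cells later pass through uncorrected).
#'
#' @param cube a biweekly `refl_cube` (the drifting stream).
#' @param delta a [compute_pics_bias()] result.
#' @param met a `met_cube` on the same axes.
#' @param min_n minimum number of years per fit (default 8).
#' @return an `sza_bias_model`: coefficient arrays `coef_red`/`coef_nir`
#'   of dim `n_pixels x 24 x 6` (a1, a2, a3, a4, a5, b), diagnostic arrays
#'   `n` and `r2`, and the anomaly climatologies needed to apply the model.
#' @export
fit_sza_bias_model <- function(cube, delta, met, min_n = 8) {
  nd <- grid_dim(cube$grid); npix <- prod(nd); nt <- nrow(cube$time)
  ord <- cube$time$ordinal

  red_a <- cube_anomaly(cube$red, ord)
  nir_a <- cube_anomaly(cube$nir, ord)
  sza_a <- cube_anomaly(cube$sza, ord)
  ta_a <- cube_anomaly(met$ta, ord)
  p_a <- cube_anomaly(met$p, ord)
  rad_a <- cube_anomaly(met$rad, ord)

  as_m <- function(a) matrix(a, npix, nt)
  red_m <- as_m(red_a); nir_m <- as_m(nir_a); sza_m <- as_m(sza_a)
  ta_m <- as_m(ta_a); p_m <- as_m(p_a); rad_m <- as_m(rad_a)

  fit_band <- function(y_m, dseries) {
    coefs <- array(NA_real_, c(npix, 24, 6))
    nfit <- array(0L, c(npix, 24)); r2 <- array(NA_real_, c(npix, 24))
    for (p in 1:24) {
      k <- which(ord == p)
      n <- length(k)
      if (n == 0) next
      xs <- list(t(sza_m[, k, drop = FALSE]),
                 matrix(dseries[k], n, npix),
                 t(ta_m[, k, drop = FALSE]),
                 t(p_m[, k, drop = FALSE]),
                 t(rad_m[, k, drop = FALSE]),
                 matrix(1, n, npix))
      res <- batched_ols(t(y_m[, k, drop = FALSE]), xs, min_n = min_n)
      coefs[, p, ] <- t(res$coef)
      nfit[, p] <- res$n
      r2[, p] <- res$r2
    }
    list(coef = coefs, n = nfit, r2 = r2)
  }
  fr <- fit_band(red_m, delta$series$delta_red)
  fn <- fit_band(nir_m, delta$series$delta_nir)

  structure(list(coef_red = fr$coef, coef_nir = fn$coef,
                 n = fr$n, r2_red = fr$r2, r2_nir = fn$r2,
                 min_n = min_n, grid = cube$grid),
            class = "sza_bias_model")
}

#' Remove the SZA-drift and inter-sensor bias contributions
#'
#' Applies the fitted model: `rho' = rho - a1 * SZA_anomaly - a2 * delta`.
#' Meteorological terms are deliberately *not* removed (genuine anomalies
#' are retained). The correction is applied to drifting (non-reference)
#' epochs only; reference-epoch time steps pass through unchanged. Pixels
#' or periods without a fitted model pass through with a flag.
#'
#' @param cube the drifting `refl_cube`.
#' @param model an [fit_sza_bias_model()] result.
#' @param delta the [compute_pics_bias()] result used in fitting.
#' @param epochs a [sensor_epoch_table()].
#' @return the corrected cube; the count of pass-through (unfitted)
#'   pixel-periods is attached as attribute `"unfitted"`.
#' @export
remove_sza_bias <- function(cube, model, delta, epochs) {
  nd <- grid_dim(cube$grid); npix <- prod(nd); nt <- nrow(cube$time)
  ord <- cube$time$ordinal
  sza_a <- cube_anomaly(cube$sza, ord)
  sza_m <- matrix(sza_a, npix, nt)
  iref <- which(epochs$reference)
  in_ref <- cube$time$year >= epochs$start_year[iref] &
    cube$time$year <= epochs$end_year[iref]

  out <- cube
  unfitted <- 0L
  for (band in c("red", "nir")) {
    cf <- if (band == "red") model$coef_red else model$coef_nir
    dser <- if (band == "red") delta$series$delta_red else delta$series$delta_nir
    bm <- matrix(out[[band]], npix, nt)
    for (k in seq_len(nt)) {
      if (in_ref[k]) next
      p <- ord[k]
      a1 <- cf[, p, 1]; a2 <- cf[, p, 2]
      corr <- a1 * sza_m[, k] + a2 * dser[k]
      ok <- is.finite(corr)
      unfitted <- unfitted + sum(!ok & is.finite(bm[, k]))
      bm[ok, k] <- bm[ok, k] - corr[ok]
    }
    out[[band]] <- array(bm, c(nd, nt))
  }
  attr(out, "unfitted") <- unfitted %/% 1L
  out
}
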