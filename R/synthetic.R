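# Synthetic-scene generation: every input the calibration and emulation
# chain needs, with the full ground truth retained so that pipeline
# estimates can be compared against the injected artifact parameters.

#' Sensor epoch lineage
#'
#' Defines which sensor observes the drifting stream in which years. Epochs
#' are non-overlapping, contiguous, and the reference-quality (drift-free)
#' epoch comes last, mirroring a NOAA-era/MetOp-era split.
#'
#' @param start_year first year of the record.
#' @param years_per_epoch integer vector of epoch lengths in years; the
#'   default `c(6, 4, 6)` gives a 16-year record whose last 6 years are
#'   also covered by the reference stream.
#' @param sensor_id epoch names.
#' @param group sensor group label used to split the windowed linear
#'   calibration (see [fit_windowed_linear()]).
#' @return a tibble with one row per epoch: `sensor_id`, `start_year`,
#'   `end_year`, `drifts`, `reference`, `group`.
#' @export
sensor_epoch_table <- function(start_year = 1982,
                               years_per_epoch = c(6, 4, 6),
                               sensor_id = c("N07", "N11", "MetOpB"),
                               group = c("noaa", "noaa", "metop")) {
  check_that(length(years_per_epoch) == length(sensor_id),
             "one sensor_id per epoch required")
  ends <- start_year + cumsum(years_per_epoch) - 1L
  starts <- c(start_year, head(ends, -1L) + 1L)
  n <- length(sensor_id)
  tibble::tibble(sensor_id = sensor_id, start_year = starts, end_year = ends,
                 drifts = c(rep(TRUE, n - 1L), FALSE),
                 reference = c(rep(FALSE, n - 1L), TRUE),
                 group = group)
}

#' Artifact injection parameters
#'
#' The per-epoch artifacts added to the drifting stream on top of the
#' surface truth: a piecewise-linear orbital SZA drift (ramping from 0 to
#' `drift_max` degrees across each epoch, resetting at epoch changes), a
#' per-band reflectance response to the drifted SZA (`a1_red`/`a1_nir`, per
#' degree), constant per-epoch inter-sensor offsets, a small linear
#' meteorological response (recoverable by the harmonization regression),
#' i.i.d. observation noise, and cloud gaps. The reference epoch has zero
#' drift and zero offset by construction.
#'
#' Defaults were chosen so that the apparent reflectance steps across the
#' two sensor switches land at roughly 5.5-8% of the ~0.4 mean reflectance
#' of bright pseudo-invariant pixels, once both the offset change and the
#' drift-induced jump are accounted for.
#'
#' @param epochs a [sensor_epoch_table()].
#' @param drift_max named vector (by sensor) of maximum SZA drift, degrees.
#' @param delta_red,delta_nir named per-epoch reflectance offsets.
#' @param a1_red,a1_nir reflectance change per degree of drifted SZA.
#' @param met_coef reflectance response per unit anomaly of Ta (deg C),
#'   P (mm) and Rad (W m-2).
#' @param noise_sd observation noise sd of the drifting stream.
#' @param noise_sd_ref observation noise sd of the reference stream.
#' @param gap_prob probability a composite is lost to clouds (drifting
#'   stream); `gap_prob_ref` for the reference stream.
#' @param gap_prob_ref reference-stream gap probability.
#' @return an `artifact_injection` list.
#' @export
artifact_injection <- function(epochs = sensor_epoch_table(),
                               drift_max = c(N07 = 10, N11 = 6, MetOpB = 0),
                               delta_red = c(N07 = 0.032, N11 = 0.018, MetOpB = 0),
                               delta_nir = c(N07 = 0.040, N11 = 0.023, MetOpB = 0),
                               a1_red = 0.0010, a1_nir = 0.0012,
                               met_coef = c(ta = 2e-4, p = -5e-5, rad = 2e-5),
                               noise_sd = 0.005, noise_sd_ref = 0.003,
                               gap_prob = 0.10, gap_prob_ref = 0.05) {
  check_that(gap_prob >= 0 && gap_prob < 1, "gap_prob must be in [0, 1)")
  ref <- epochs$sensor_id[epochs$reference]
  check_that(all(drift_max[ref] == 0) && all(delta_red[ref] == 0) &&
               all(delta_nir[ref] == 0),
             "reference epoch must have zero drift and zero offset")
  structure(list(drift_max = drift_max, delta_red = delta_red,
                 delta_nir = delta_nir, a1_red = a1_red, a1_nir = a1_nir,
                 met_coef = met_coef, noise_sd = noise_sd,
                 noise_sd_ref = noise_sd_ref, gap_prob = gap_prob,
                 gap_prob_ref = gap_prob_ref),
            class = "artifact_injection")
}

# per-class centers for the surface truth harmonics
lc_class_table <- function() {
  tibble::tribble(
    ~class, ~red_mean, ~nir_mean, ~red_amp, ~nir_amp,
    "NF",   0.050, 0.280, 0.010, 0.050,
    "EBF",  0.040, 0.320, 0.005, 0.030,
    "DBF",  0.055, 0.300, 0.020, 0.090,
    "MF",   0.050, 0.290, 0.015, 0.070,
    "SH",   0.120, 0.220, 0.015, 0.040,
    "SAV",  0.100, 0.250, 0.025, 0.060,
    "GRA",  0.080, 0.260, 0.025, 0.080,
    "CRO",  0.070, 0.280, 0.030, 0.100)
}

#' Surface truth model
#'
#' Per-pixel harmonic ground truth for the red and NIR bands: a mean, an
#' annual and a semiannual harmonic, and a small interannual trend, plus a
#' land-cover label. A configurable number of pixels are bright, aseasonal,
#' trend-free pseudo-invariant (PICS) targets.
#'
#' @param grid a [grid_spec()].
#' @param n_pics number of pseudo-invariant pixels (half are reserved for
#'   validation by downstream helpers).
#' @param seed integer seed.
#' @return a `surface_truth` object carrying per-pixel coefficient
#'   matrices, the class matrix and `pics_idx` (linear pixel indices).
#' @export
surface_truth_model <- function(grid, n_pics = 20, seed = 1) {
  nd <- grid_dim(grid)
  npix <- prod(nd)
  check_that(n_pics < npix, "more PICS pixels than grid cells")
  tab <- lc_class_table()
  with_seed(seed, {
    cls <- sample(tab$class, npix, replace = TRUE)
    pics_idx <- sample.int(npix, n_pics)
    cls[pics_idx] <- "PICS"
    row <- match(cls, tab$class)
    jit <- function(x, s) x + rnorm(npix, 0, s)
    red_mean <- jit(tab$red_mean[row], 0.008)
    nir_mean <- jit(tab$nir_mean[row], 0.02)
    red_amp1 <- pmax(jit(tab$red_amp[row], 0.004), 0)
    nir_amp1 <- pmax(jit(tab$nir_amp[row], 0.012), 0)
    red_amp2 <- red_amp1 * runif(npix, 0.1, 0.35)
    nir_amp2 <- nir_amp1 * runif(npix, 0.1, 0.35)
    phase1 <- runif(npix, 12, 16)       # peak period-of-year (summer-ish)
    phase2 <- runif(npix, 1, 24)
    red_trend <- rnorm(npix, 0, 2e-4)   # per year
    nir_trend <- rnorm(npix, 2e-4, 4e-4)
    # PICS: bright, flat, stable
    red_mean[pics_idx] <- 0.40 + rnorm(n_pics, 0, 0.01)
    nir_mean[pics_idx] <- 0.44 + rnorm(n_pics, 0, 0.01)
    for (v in c("red_amp1", "nir_amp1", "red_amp2", "nir_amp2",
                "red_trend", "nir_trend"))
      assign(v, replace(get(v), pics_idx, 0))
  })
  shape <- function(x) matrix(x, nd[1], nd[2])
  structure(list(grid = grid, class = shape(cls), pics_idx = sort(pics_idx),
                 red_mean = shape(red_mean), nir_mean = shape(nir_mean),
                 red_amp1 = shape(red_amp1), nir_amp1 = shape(nir_amp1),
                 red_amp2 = shape(red_amp2), nir_amp2 = shape(nir_amp2),
                 phase1 = shape(phase1), phase2 = shape(phase2),
                 red_trend = shape(red_trend), nir_trend = shape(nir_trend)),
            class = "surface_truth")
}

# evaluate the truth harmonics on a biweekly time table -> list(red, nir)
truth_reflectance <- function(truth, time) {
  nd <- grid_dim(truth$grid)
  nt <- nrow(time)
  y0 <- min(time$year)
  red <- nir <- array(NA_real_, c(nd, nt))
  for (k in seq_len(nt)) {
    p <- time$ordinal[k]; dy <- time$year[k] - y0
    c1 <- cos(2 * pi * (p - truth$phase1) / 24)
    c2 <- cos(4 * pi * (p - truth$phase2) / 24)
    red[, , k] <- truth$red_mean + truth$red_amp1 * c1 +
      truth$red_amp2 * c2 + truth$red_trend * dy
    nir[, , k] <- truth$nir_mean + truth$nir_amp1 * c1 +
      truth$nir_amp2 * c2 + truth$nir_trend * dy
  }
  list(red = pmin(pmax(red, 0.01), 0.95), nir = pmin(pmax(nir, 0.01), 0.95))
}

# linear SZA drift profile across each epoch (0 at epoch start to drift_max
# at epoch end), evaluated on a biweekly time table; returns vector length nt
sza_drift_profile <- function(time, epochs, drift_max) {
  drift <- numeric(nrow(time))
  for (i in seq_len(nrow(epochs))) {
    in_ep <- time$year >= epochs$start_year[i] & time$year <= epochs$end_year[i]
    if (!any(in_ep)) next
    k <- which(in_ep)
    frac <- (seq_along(k) - 1) / max(length(k) - 1, 1)
    drift[k] <- frac * (drift_max[[epochs$sensor_id[i]]] %||% 0)
  }
  drift
}

epoch_of_year <- function(year, epochs) {
  out <- rep(NA_integer_, length(year))
  for (i in seq_len(nrow(epochs)))
    out[year >= epochs$start_year[i] & year <= epochs$end_year[i]] <- i
  out
}

#' Simulate meteorological covariates
#'
#' Smooth seasonal air temperature and radiation, stochastic precipitation,
#' aerosol optical depth, snow depth and cloud cover, and static elevation
#' and aridity-index fields, on the same grid/time axes as the reflectance
#' record. These same fields drive the (small) meteorological response of
#' the simulated drifting stream, so the harmonization regression terms are
#' recoverable.
#'
#' @param grid a [grid_spec()].
#' @param time a biweekly time table ([biweekly_seq()]).
#' @param seed integer seed.
#' @return a `met_cube`.
#' @export
simulate_covariates <- function(grid, time, seed = 1) {
  nd <- grid_dim(grid)
  nt <- nrow(time)
  npix <- prod(nd)
  lat <- matrix(grid$lat, nd[1], nd[2])
  with_seed(seed, {
    smooth_field <- function(scale) {
      f <- matrix(0, nd[1], nd[2])
      for (m in 1:3) {
        fx <- runif(1, 0.5, 2); fy <- runif(1, 0.5, 2)
        ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
        f <- f + rnorm(1, 0, scale) *
          outer(cos(fx * seq_len(nd[1]) / nd[1] * 2 * pi + ph1),
                cos(fy * seq_len(nd[2]) / nd[2] * 2 * pi + ph2))
      }
      f
    }
    seas <- function(amp_sign) cos(2 * pi * (time$ordinal - 13.5) / 24) * amp_sign
    ta <- aod <- cc <- p <- rad <- sdp <- array(NA_real_, c(nd, nt))
    hemi <- sign(lat); hemi[hemi == 0] <- 1
    ta_mean <- 12 + smooth_field(2) - 0.3 * abs(lat - mean(lat))
    for (k in seq_len(nt)) {
      s <- cos(2 * pi * (time$ordinal[k] - 13.5) / 24)
      ta[, , k] <- ta_mean + 11 * s * hemi + rnorm(npix, 0, 1.5)
      rad[, , k] <- pmax(180 + 110 * s * hemi + rnorm(npix, 0, 12), 5)
      p[, , k] <- stats::rgamma(npix, shape = 2, scale = 12)
      aod[, , k] <- exp(rnorm(npix, log(0.15), 0.4))
      cc[, , k] <- stats::rbeta(npix, 2.2, 2.0)
      sdp[, , k] <- pmax(-ta[, , k], 0) * 0.01 * stats::rbeta(npix, 2, 2)
    }
    ele <- pmax(300 + smooth_field(250), 0)
    ai <- pmax(0.6 + smooth_field(0.4), 0.05)
  })
  new_cube(grid, time, ta = ta, p = p, rad = rad, aod = aod, sd = sdp,
           cc = cc, ele = ele, ai = ai, class = "met_cube")
}

#' Simulate the multi-sensor reflectance scene
#'
#' Generates the drifting-sensor stream (truth + SZA-drift response +
#' per-epoch inter-sensor offsets + meteorological response + noise, with
#' cloud gaps), the drift-free reference stream over its availability
#' window (truth + noise), and the covariate cube, bundling all truth
#' parameters for parameter-recovery tests.
#'
#' At `cadence = "biweekly"` the generator emits composite-level
#' observations directly; `cadence = "daily"` emits daily grids (for
#' compositing tests) with the per-day solar zenith angle and QC, to be fed
#' through [qc_filter()] and [composite_mvc()].
#'
#' @param truth a [surface_truth_model()].
#' @param inject an [artifact_injection()].
#' @param epochs a [sensor_epoch_table()].
#' @param seed integer seed.
#' @param cadence `"biweekly"` or `"daily"`.
#' @param ref_years years covered by the reference stream (default: the
#'   reference epoch's years).
#' @param overpass_lst nominal local solar overpass time, hours.
#' @return an `lcspp_scene` list: `drifting`, `reference` (`refl_cube`s;
#'   daily lists at daily cadence), `met`, `truth_red`/`truth_nir` arrays,
#'   plus the generator inputs.
#' @export
simulate_scene <- function(truth, inject = artifact_injection(),
                           epochs = sensor_epoch_table(), seed = 1,
                           cadence = c("biweekly", "daily"),
                           ref_years = NULL, overpass_lst = 13.6) {
  cadence <- match.arg(cadence)
  grid <- truth$grid
  nd <- grid_dim(grid)
  npix <- prod(nd)
  if (is.null(ref_years)) {
    i <- which(epochs$reference)
    ref_years <- seq.int(epochs$start_year[i], epochs$end_year[i])
  }
  time <- biweekly_seq(min(epochs$start_year), max(epochs$end_year))
  nt <- nrow(time)
  tr <- truth_reflectance(truth, time)
  met <- simulate_covariates(grid, time, seed = seed + 1L)

  # per-pixel-period climatological met anomalies drive the injected response
  anom <- function(a) a - clim_expand(clim_mean(a, time$ordinal), time$ordinal)
  ta_a <- anom(met$ta); p_a <- anom(met$p); rad_a <- anom(met$rad)

  doy <- period_mid_doy(time)
  nominal_sza <- array(NA_real_, c(nd, nt))
  for (k in seq_len(nt)) {
    mu <- cos_sza(grid$lat, doy[k], overpass_lst)
    nominal_sza[, , k] <- matrix(acos(pmin(pmax(mu, 0.01), 1)) * 180 / pi,
                                 nd[1], nd[2])
  }
  drift <- sza_drift_profile(time, epochs, inject$drift_max)
  ep_idx <- epoch_of_year(time$year, epochs)
  sensor <- epochs$sensor_id[ep_idx]

  if (cadence == "daily") {
    return(simulate_scene_daily(truth, inject, epochs, seed, ref_years,
                                overpass_lst, met))
  }

  with_seed(seed, {
    mk_band <- function(true, a1, delta, mc) {
      obs <- true
      for (k in seq_len(nt)) {
        obs[, , k] <- obs[, , k] + a1 * drift[k] + delta[[sensor[k]]] +
          mc[["ta"]] * ta_a[, , k] + mc[["p"]] * p_a[, , k] +
          mc[["rad"]] * rad_a[, , k]
      }
      obs + rnorm(length(obs), 0, inject$noise_sd)
    }
    red_obs <- mk_band(tr$red, inject$a1_red, inject$delta_red, inject$met_coef)
    nir_obs <- mk_band(tr$nir, inject$a1_nir, inject$delta_nir, inject$met_coef)
    gap <- array(runif(npix * nt) < inject$gap_prob, c(nd, nt))
    qc <- array(0L, c(nd, nt)); qc[gap] <- qc_bits[["cloud"]]
    red_obs[gap] <- NaN; nir_obs[gap] <- NaN
    sza_obs <- nominal_sza + rep(drift, each = npix)
    sza_obs[gap] <- NaN

    in_ref <- time$year %in% ref_years
    ref_red <- tr$red + rnorm(npix * nt, 0, inject$noise_sd_ref)
    ref_nir <- tr$nir + rnorm(npix * nt, 0, inject$noise_sd_ref)
    ref_gap <- array(runif(npix * nt) < inject$gap_prob_ref, c(nd, nt))
    ref_gap[, , !in_ref] <- TRUE
    ref_qc <- array(0L, c(nd, nt)); ref_qc[ref_gap] <- qc_bits[["cloud"]]
    ref_red[ref_gap] <- NaN; ref_nir[ref_gap] <- NaN
  })

  drifting <- new_cube(grid, time, red = red_obs, nir = nir_obs,
                       sza = sza_obs, qc = qc, sensor_id = sensor,
                       class = "refl_cube")
  reference <- new_cube(grid, time, red = ref_red, nir = ref_nir,
                        sza = nominal_sza, qc = ref_qc,
                        sensor_id = rep("REF", nt), class = "refl_cube")
  structure(list(drifting = drifting, reference = reference, met = met,
                 truth_red = tr$red, truth_nir = tr$nir,
                 nominal_sza = nominal_sza, drift = drift,
                 truth = truth, inject = inject, epochs = epochs,
                 ref_years = ref_years, seed = seed),
            class = "lcspp_scene")
}

# daily-cadence variant: small grids only; emits day-level observations of a
# within-period-constant truth so MVC recovers the truth exactly at zero noise
simulate_scene_daily <- function(truth, inject, epochs, seed, ref_years,
                                 overpass_lst, met) {
  grid <- truth$grid
  nd <- grid_dim(grid)
  npix <- prod(nd)
  dates <- seq(as.Date(sprintf("%d-01-01", min(epochs$start_year))),
               as.Date(sprintf("%d-12-31", max(epochs$end_year))), by = "1 day")
  idx <- biweekly_index_of(dates)
  time <- biweekly_seq(min(epochs$start_year), max(epochs$end_year))
  period_of_day <- match(paste(idx$year, idx$ordinal),
                         paste(time$year, time$ordinal))
  nday <- length(dates)
  tr <- truth_reflectance(truth, time)
  drift_bw <- sza_drift_profile(time, epochs, inject$drift_max)
  ep_idx <- epoch_of_year(idx$year, epochs)
  sensor <- epochs$sensor_id[ep_idx]
  doy <- as.integer(format(dates, "%j"))

  with_seed(seed, {
    red <- nir <- sza <- array(NA_real_, c(nd, nday))
    qc <- array(0L, c(nd, nday))
    for (d in seq_len(nday)) {
      k <- period_of_day[d]
      mu <- cos_sza(grid$lat, doy[d], overpass_lst)
      base_sza <- matrix(acos(pmin(pmax(mu, 0.01), 1)) * 180 / pi, nd[1], nd[2])
      dr <- drift_bw[k]
      red[, , d] <- tr$red[, , k] + inject$a1_red * dr +
        inject$delta_red[[sensor[d]]] + rnorm(npix, 0, inject$noise_sd)
      nir[, , d] <- tr$nir[, , k] + inject$a1_nir * dr +
        inject$delta_nir[[sensor[d]]] + rnorm(npix, 0, inject$noise_sd)
      sza[, , d] <- base_sza + dr
      gap <- runif(npix) < inject$gap_prob
      qc[, , d][gap] <- qc_bits[["cloud"]]
    }
    red[qc != 0L] <- NaN; nir[qc != 0L] <- NaN; sza[qc != 0L] <- NaN
  })
  structure(list(
    drifting = list(grid = grid, date = dates, red = red, nir = nir,
                    sza = sza, qc = qc, sensor_id = sensor),
    met = met, truth_red = tr$red, truth_nir = tr$nir, time = time,
    truth = truth, inject = inject, epochs = epochs, ref_years = ref_years,
    seed = seed), class = "lcspp_scene_daily")
}

#' Split the truth's pseudo-invariant pixels into calibration/validation sets
#'
#' @param truth a `surface_truth`.
#' @return list with `calibration` and `validation` linear pixel indices
#'   (disjoint halves of the truth's PICS set).
#' @export
pics_sets <- function(truth) {
  n <- length(truth$pics_idx)
  check_that(n >= 2, "need at least 2 PICS pixels to split")
  half <- n %/% 2
  list(calibration = truth$pics_idx[seq_len(half)],
       validation = truth$pics_idx[(half + 1):n])
}

#' SIF generating law for the synthetic soundings
#'
#' The default law ties true SIF to the chlorophyll-absorbed-radiation
#' proxy: `SIF = s * cos(SZA) * NIRv + intercept`, with NIRv computed from
#' the truth reflectance. Per-sounding retrieval noise is i.i.d. Gaussian.
#'
#' The default slope and noise put the aggregated (>= 5 soundings/cell)
#' targets at a signal-to-noise ratio where the cell-mean noise variance is
#' a few percent of the SIF signal variance - the clean training regime the
#' emulator recovery analysis is defined on; single soundings span roughly
#' 0-1.5 mW m-2 nm-1 sr-1 as for far-red SIF retrievals.
#'
#' @param s slope against `cosSZA * NIRv` (mW m-2 nm-1 sr-1).
#' @param intercept additive offset.
#' @param noise_sd single-sounding retrieval noise sd (mW m-2 nm-1 sr-1).
#' @param fun optional custom generating function
#'   `f(red, nir, cos_sza) -> sif` overriding the default law.
#' @return a `sif_truth` object.
#' @export
sif_truth_model <- function(s = 5.0, intercept = 0.05, noise_sd = 0.15,
                            fun = NULL) {
  check_that(noise_sd >= 0, "noise_sd must be >= 0")
  f <- fun %||% function(red, nir, cos_sza) {
    ndvi <- (nir - red) / (nir + red)
    pmax(s * cos_sza * ndvi * nir + intercept, 0)
  }
  structure(list(s = s, intercept = intercept, noise_sd = noise_sd, fun = f),
            class = "sif_truth")
}

#' Simulate satellite SIF soundings
#'
#' Point soundings at a nominal early-afternoon overpass: on each day a
#' random subset of grid cells is "overflown" and receives a clustered
#' number of soundings; each sounding draws true SIF from the generating
#' law at the cell's truth reflectance and date geometry, plus retrieval
#' noise. A configurable fraction of soundings fails the quality screen and
#' a small fraction is non-nadir.
#'
#' @param truth a [surface_truth_model()].
#' @param sif a [sif_truth_model()].
#' @param years year range covered by the soundings.
#' @param seed integer seed.
#' @param cell_frac fraction of grid cells observed per day.
#' @param count_lambda soundings per observed cell are `1 + Poisson(count_lambda)`.
#' @param flag_fail_frac fraction failing the quality flag.
#' @param glint_frac fraction in non-nadir (glint) mode.
#' @param overpass_lst nominal local solar time of the overpass.
#' @param days_per_period sampled days per biweekly period (default 3).
#' @return a tibble of soundings: `lat`, `lon`, `date`, `sif_757`, `sza`,
#'   `quality_flag` (0 best), `mode` ("nadir"/"glint"), `cloud_flag`,
#'   plus the generator's `sif_true`, matched `red`/`nir` truth and the
#'   originating `cell` index.
#' @export
simulate_soundings <- function(truth, sif = sif_truth_model(),
                               years = c(2015, 2022), seed = 1,
                               cell_frac = 0.15, count_lambda = 8,
                               flag_fail_frac = 0.10, glint_frac = 0.05,
                               overpass_lst = 13.6, days_per_period = 3) {
  grid <- truth$grid
  nd <- grid_dim(grid)
  npix <- prod(nd)
  time <- biweekly_seq(years[1], years[2])
  tr <- truth_reflectance(truth, time)
  latm <- matrix(grid$lat, nd[1], nd[2])
  lonm <- matrix(grid$lon, nd[1], nd[2], byrow = TRUE)

  with_seed(seed, {
    rows <- list()
    ridx <- 0L
    for (k in seq_len(nrow(time))) {
      base <- time$mid_date[k]
      days <- base + sample(-6:6, days_per_period)
      for (d in as.list(days)) {
        cells <- which(runif(npix) < cell_frac)
        if (length(cells) == 0) next
        counts <- 1L + rpois(length(cells), count_lambda)
        cell <- rep(cells, counts)
        n <- length(cell)
        doy <- as.integer(format(as.Date(d, origin = "1970-01-01"), "%j"))
        mu <- cos_sza(latm[cell], doy, overpass_lst)
        mu <- pmax(mu, 0.05)
        red <- tr$red[, , k][cell]; nir <- tr$nir[, , k][cell]
        s_true <- sif$fun(red, nir, mu)
        ridx <- ridx + 1L
        rows[[ridx]] <- tibble::tibble(
          cell = cell, lat = latm[cell], lon = lonm[cell],
          date = as.Date(d, origin = "1970-01-01"),
          sza = acos(mu) * 180 / pi,
          sif_true = s_true, red = red, nir = nir,
          sif_757 = s_true + rnorm(n, 0, sif$noise_sd),
          quality_flag = ifelse(runif(n) < flag_fail_frac, 1L, 0L),
          mode = ifelse(runif(n) < glint_frac, "glint", "nadir"),
          cloud_flag = 0L)
      }
    }
  })
  dplyr::bind_rows(rows)
}

#' Simulate site-level GPP linked to the true SIF signal
#'
#' Biweekly GPP at a set of "tower" pixels, generated as a per-land-cover
#' linear scaling of the true SIF signal at the site plus noise, with a
#' per-period quality-control fraction emulating gap-filled flux data.
#'
#' @param truth a [surface_truth_model()].
#' @param sif a [sif_truth_model()].
#' @param sites integer vector of linear pixel indices.
#' @param years year range.
#' @param seed integer seed.
#' @param alpha named per-class GPP/SIF scaling (g C m-2 d-1 per
#'   mW m-2 nm-1 sr-1); unnamed classes fall back to 12.
#' @param noise_sd GPP observation noise sd.
#' @param overpass_lst local solar time defining the SIF geometry.
#' @return a tibble: `site`, `cell`, `class`, `year`, `ordinal`, `index`,
#'   `gpp`, `qc` (fraction of good data in the period) and the generator's
#'   `sif_true`.
#' @export
simulate_site_gpp <- function(truth, sif = sif_truth_model(), sites,
                              years = c(2001, 2010), seed = 1,
                              alpha = c(NF = 10, EBF = 14, DBF = 12, MF = 11,
                                        SH = 8, SAV = 9, GRA = 10, CRO = 13),
                              noise_sd = 1.0, overpass_lst = 13.6) {
  grid <- truth$grid
  nd <- grid_dim(grid)
  check_that(all(sites >= 1 & sites <= prod(nd)), "site index out of range")
  time <- biweekly_seq(years[1], years[2])
  tr <- truth_reflectance(truth, time)
  latm <- matrix(grid$lat, nd[1], nd[2])
  doy <- period_mid_doy(time)
  with_seed(seed, {
    out <- purrr::map_dfr(seq_along(sites), function(si) {
      cell <- sites[si]
      cls <- truth$class[cell]
      a <- alpha[[cls]] %||% 12
      mu <- pmax(cos_sza(latm[cell], doy, overpass_lst), 0)
      red <- vapply(seq_len(nrow(time)), function(k) tr$red[, , k][cell],
                    numeric(1))
      nir <- vapply(seq_len(nrow(time)), function(k) tr$nir[, , k][cell],
                    numeric(1))
      s_true <- sif$fun(red, nir, mu)
      tibble::tibble(site = si, cell = cell, class = cls,
                     year = time$year, ordinal = time$ordinal,
                     index = time$index, sif_true = s_true,
                     gpp = a * s_true + rnorm(nrow(time), 0, noise_sd),
                     qc = stats::rbeta(nrow(time), 5, 1))
    })
  })
  out
}
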