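# Technical-validation computations: vegetation indices, accuracy metrics,
# pseudo-invariant site diagnostics, trend estimation/testing, masks, and
# the site-level GPP comparison.

#' Vegetation indices from red and NIR reflectance
#'
#' `NDVI = (nir - red)/(nir + red)`; `kNDVI = tanh(((nir - red)/(2*sigma))^2)`
#' with the per-element default `sigma = 0.5*(nir + red)`, which makes
#' `kNDVI = tanh(NDVI^2)`; `NIRv = NDVI * nir`; `NIRvP = NIRv * rad`.
#'
#' @param red,nir reflectance in `[0, 1]`.
#' @param rad optional downward solar radiation (W m-2), required for NIRvP.
#' @param sigma kNDVI kernel length scale; default `0.5*(nir + red)`.
#' @return a tibble with columns `ndvi`, `kndvi`, `nirv` (and `nirvp` when
#'   `rad` is given). Elements with `nir + red = 0` are `NA`.
#' @export
vegetation_indices <- function(red, nir, rad = NULL, sigma = NULL) {
  denom <- nir + red
  ndvi <- ifelse(denom == 0, NA_real_, (nir - red) / denom)
  if (is.null(sigma)) sigma <- 0.5 * denom
  kndvi <- ifelse(denom == 0, NA_real_, tanh(((nir - red) / (2 * sigma))^2))
  nirv <- ndvi * nir
  out <- tibble::tibble(ndvi = as.vector(ndvi), kndvi = as.vector(kndvi),
                        nirv = as.vector(nirv))
  if (!is.null(rad)) out$nirvp <- out$nirv * as.vector(rad)
  out
}

#' Accuracy metrics
#'
#' Nash-Sutcliffe efficiency `1 - sum((pred-obs)^2)/sum((obs-mean(obs))^2)`,
#' root-mean-square error, and squared Pearson correlation. Pairs with a
#' missing value on either side are dropped.
#'
#' @param pred,obs numeric vectors of equal length.
#' @return a scalar.
#' @export
nse <- function(pred, obs) {
  ok <- is.finite(pred) & is.finite(obs)
  check_that(sum(ok) >= 2, "need at least 2 valid pairs")
  obs <- obs[ok]; pred <- pred[ok]
  den <- sum((obs - mean(obs))^2)
  check_that(den > 0, "NSE undefined: observations have zero variance")
  1 - sum((pred - obs)^2) / den
}

#' @rdname nse
#' @export
rmse <- function(pred, obs) {
  ok <- is.finite(pred) & is.finite(obs)
  check_that(sum(ok) >= 1, "need at least 1 valid pair")
  sqrt(mean((pred[ok] - obs[ok])^2))
}

#' @rdname nse
#' @param x,y numeric vectors (for `r2`).
#' @export
r2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  check_that(sum(ok) >= 2, "need at least 2 valid pairs")
  if (var(x[ok]) == 0 || var(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

#' Pseudo-invariant site diagnostics of a calibrated record
#'
#' At a held-out set of pseudo-invariant pixels: (a) annual mean
#' reflectance per band, linearly detrended and normalized by the series
#' mean (anomalies in percent); (b) the discontinuity at each sensor
#' switch, `|mean(12 months after) - mean(12 months before)| / series mean`
#' in percent; (c) optionally, the Pearson correlation between the annual
#' anomalies and the annual anomalies of a global product series.
#'
#' @param cube a calibrated `refl_cube`.
#' @param validation_pics linear pixel indices (disjoint from the
#'   calibration set).
#' @param epochs a [sensor_epoch_table()]; switches are the epoch
#'   boundaries.
#' @param product optional tibble `year`, `value` of global product means.
#' @return a `pics_diagnostics` list: `anomalies` (tibble `year`, `band`,
#'   `anomaly_pct`), `discontinuities` (tibble `switch`, `band`,
#'   `discontinuity_pct`), and `product_correlation` when `product` given.
#' @export
pics_diagnostics <- function(cube, validation_pics, epochs, product = NULL) {
  nd <- grid_dim(cube$grid); npix <- prod(nd); nt <- nrow(cube$time)
  years <- sort(unique(cube$time$year))

  band_series <- function(band) {
    m <- matrix(cube[[band]], npix, nt)[validation_pics, , drop = FALSE]
    colMeans(m, na.rm = TRUE)
  }

  anom <- list(); disc <- list(); corr <- list()
  for (band in c("red", "nir")) {
    s <- band_series(band)
    annual <- vapply(years, function(y)
      mean(s[cube$time$year == y], na.rm = TRUE), numeric(1))
    mu <- mean(annual, na.rm = TRUE)
    dt <- stats::residuals(lm(annual ~ years, na.action = stats::na.exclude))
    anom[[band]] <- tibble::tibble(year = years, band = band,
                                   anomaly_pct = 100 * dt / mu)
    if (nrow(epochs) > 1) {
      for (i in seq_len(nrow(epochs) - 1L)) {
        before <- cube$time$year %in%
          (epochs$end_year[i] - 0):(epochs$end_year[i])
        after <- cube$time$year %in%
          (epochs$start_year[i + 1]):(epochs$start_year[i + 1] + 0)
        if (sum(before) < 12 || sum(after) < 12) next
        d <- abs(mean(s[after], na.rm = TRUE) - mean(s[before], na.rm = TRUE))
        disc[[paste(band, i)]] <- tibble::tibble(
          switch = sprintf("%s->%s", epochs$sensor_id[i],
                           epochs$sensor_id[i + 1]),
          band = band, discontinuity_pct = 100 * d / mean(s, na.rm = TRUE))
      }
    }
    if (!is.null(product)) {
      common <- intersect(years, product$year)
      a <- anom[[band]]$anomaly_pct[match(common, years)]
      pv <- product$value[match(common, product$year)]
      pa <- stats::residuals(lm(pv ~ common))
      ct <- stats::cor.test(a, pa)
      corr[[band]] <- tibble::tibble(band = band, r = unname(ct$estimate),
                                     p_value = ct$p.value, n = length(common))
    }
  }
  structure(list(anomalies = dplyr::bind_rows(anom),
                 discontinuities = dplyr::bind_rows(disc),
                 product_correlation =
                   if (length(corr)) dplyr::bind_rows(corr) else NULL),
            class = "pics_diagnostics")
}

#' Linear (OLS) trend of an annual series
#'
#' @param values annual values.
#' @param years corresponding years (default sequential).
#' @return a `lcspp_trend` tibble row: `slope_per_decade`, `intercept`,
#'   `p_value`, `method`, `n`.
#' @export
trend_ols <- function(values, years = seq_along(values)) {
  ok <- is.finite(values) & is.finite(years)
  check_that(sum(ok) >= 4, "need at least 4 annual values")
  fit <- lm(values[ok] ~ years[ok])
  sm <- suppressWarnings(summary(fit))  # noiseless input is legitimate here
  structure(tibble::tibble(slope_per_decade = 10 * coef(fit)[[2]],
                           intercept = coef(fit)[[1]],
                           p_value = sm$coefficients[2, 4],
                           method = "ols", n = sum(ok)),
            class = c("lcspp_trend", "tbl_df", "tbl", "data.frame"))
}

# Mann-Kendall S statistic and tie-corrected variance
mk_s_var <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) s <- s + sum(sign(x[(i + 1):n] - x[i]))
  ties <- table(x)
  tie_term <- sum(ties * (ties - 1) * (2 * ties + 5))
  v <- (n * (n - 1) * (2 * n + 5) - tie_term) / 18
  list(s = s, var = v)
}

mk_p <- function(s, v) {
  if (v <= 0) return(1)
  z <- if (s > 0) (s - 1) / sqrt(v) else if (s < 0) (s + 1) / sqrt(v) else 0
  2 * pnorm(-abs(z))
}

#' Theil-Sen trend with an autocorrelation-corrected Mann-Kendall test
#'
#' Slope is the median of all pairwise slopes. Significance comes from the
#' Mann-Kendall S statistic whose variance is inflated by the Hamed-Rao
#' correction factor
#' `n/n* = 1 + 2/(n(n-1)(n-2)) * sum (n-i)(n-i-1)(n-i-2) rho_i`,
#' computed from the lag autocorrelations of the ranks of the Theil-Sen
#' detrended series. Lags are screened at `alpha_lag` (two-sided normal
#' bounds); when the lag-1 rank autocorrelation is significantly positive,
#' the correlation structure is extended geometrically over all lags from
#' a small-sample bias-adjusted lag-1 estimate (an AR(1) extension;
#' restricting the factor to the few individually significant lags is
#' known to under-correct and over-reject under serial correlation).
#' Otherwise only individually significant low-order lags contribute.
#'
#' @param values annual values.
#' @param years corresponding years.
#' @param alpha_lag screening level for rank autocorrelations (default 0.05).
#' @param max_lag highest individually screened lag (default 3).
#' @return a `lcspp_trend` tibble row (`method = "theil_sen_mk"`).
#' @export
trend_theil_sen_mk <- function(values, years = seq_along(values),
                               alpha_lag = 0.05, max_lag = 3) {
  ok <- is.finite(values) & is.finite(years)
  check_that(sum(ok) >= 8, "need at least 8 annual values")
  x <- values[ok]; t <- years[ok]
  o <- order(t); x <- x[o]; t <- t[o]
  n <- length(x)

  pair_slopes <- unlist(lapply(seq_len(n - 1), function(i) {
    (x[(i + 1):n] - x[i]) / (t[(i + 1):n] - t[i])
  }))
  slope <- median(pair_slopes, na.rm = TRUE)
  intercept <- median(x - slope * t)

  mk <- mk_s_var(x)
  rk <- rank(x - slope * t)
  nl <- max(1L, min(10L, n - 3L))
  rho <- stats::acf(rk, lag.max = nl, plot = FALSE, demean = TRUE)$acf[-1]
  crit <- qnorm(1 - alpha_lag / 2) / sqrt(n)
  lags <- seq_len(n - 3L)
  if (is.finite(rho[1]) && rho[1] > crit) {
    r1 <- min(0.99, rho[1] + (1 + 4 * rho[1]) / n)
    rs <- r1^lags
  } else {
    rs <- rep(0, n - 3L)
    sig <- is.finite(rho) & abs(rho) > crit & seq_along(rho) <= max_lag
    rs[seq_along(rho)][sig] <- rho[sig]
  }
  factor_corr <- 1 + 2 / (n * (n - 1) * (n - 2)) *
    sum((n - lags) * (n - lags - 1) * (n - lags - 2) * rs)
  factor_corr <- max(factor_corr, 1e-8)
  v <- mk$var * factor_corr
  p <- if (mk$s == 0 && all(diff(x) == 0)) 1 else mk_p(mk$s, v)

  structure(tibble::tibble(slope_per_decade = 10 * slope,
                           intercept = intercept, p_value = p,
                           method = "theil_sen_mk", n = n),
            class = c("lcspp_trend", "tbl_df", "tbl", "data.frame"))
}

#' @method tidy lcspp_trend
#' @export
tidy.lcspp_trend <- function(x, ...) tibble::as_tibble(unclass(x))

#' Growing-season mask from a monthly temperature climatology
#'
#' A pixel-month is in the growing season iff its climatological mean air
#' temperature is strictly above 5 degrees C.
#'
#' @param ta_climatology array `lat x lon x 12` of monthly mean Ta (deg C).
#' @param threshold_c temperature threshold (default 5).
#' @return logical array of the same shape.
#' @export
growing_season_mask <- function(ta_climatology, threshold_c = 5) {
  ta_climatology > threshold_c
}

#' Area-weighted spatial mean
#'
#' Aggregation weights are proportional to `cos(latitude)` of the cell
#' center; masked-out or missing cells are excluded.
#'
#' @param field matrix `lat x lon` (or array `lat x lon x k`).
#' @param lat latitude centers (degrees) matching the rows.
#' @param mask optional logical matrix/array; `FALSE` excludes a cell.
#' @return a scalar (or length-k vector for an array input).
#' @export
area_weighted_mean <- function(field, lat, mask = NULL) {
  w2 <- matrix(cos(lat * pi / 180), nrow = length(lat),
               ncol = if (is.matrix(field)) ncol(field) else dim(field)[2])
  one <- function(f, m) {
    use <- is.finite(f) & (if (is.null(m)) TRUE else m)
    if (!any(use)) return(NA_real_)
    sum(f[use] * w2[use]) / sum(w2[use])
  }
  if (is.matrix(field)) return(one(field, mask))
  vapply(seq_len(dim(field)[3]), function(k)
    one(field[, , k], if (is.null(mask)) NULL else
      if (length(dim(mask)) == 3) mask[, , k] else mask), numeric(1))
}

#' Low-signal mask for trend/correlation maps
#'
#' Pixels whose multi-year mean is below the threshold (default 0.03
#' mW m-2 nm-1 sr-1) are excluded (strict `<`).
#'
#' @param climatology matrix `lat x lon` of multi-year means.
#' @param threshold exclusion threshold.
#' @return logical matrix, `TRUE` = retained.
#' @export
low_signal_mask <- function(climatology, threshold = 0.03) {
  !(is.na(climatology) | climatology < threshold)
}

#' Site-level GPP comparison across photosynthesis proxies
#'
#' Biweekly periods qualify when their flux-data quality fraction exceeds
#' `qc_threshold` (strict `>`). Per site and proxy, the squared Pearson
#' correlation with GPP is computed over qualifying periods; proxies are
#' then compared with paired t-tests across sites within each land-cover
#' class. With `era_year` set, sites are additionally split into pre/post
#' eras and only sites with at least `min_years` distinct years of
#' qualifying data in *both* eras enter the era comparison.
#'
#' @param proxies long tibble: `site`, `index` (period), `proxy`, `value`.
#' @param gpp tibble from [simulate_site_gpp()]: `site`, `class`, `index`,
#'   `year`, `gpp`, `qc`.
#' @param qc_threshold quality threshold (default 0.7).
#' @param era_year optional split year (periods with `year < era_year` are
#'   the early era).
#' @param min_years minimum qualifying years per era (default 3).
#' @param alpha significance level for the paired tests.
#' @return a list: `sites` (per site x proxy x era R-squared tibble),
#'   `tests` (pairwise paired t-tests by class), `dropped_periods`.
#' @export
site_gpp_comparison <- function(proxies, gpp, qc_threshold = 0.7,
                                era_year = NULL, min_years = 3,
                                alpha = 0.05) {
  qualified <- dplyr::filter(gpp, .data$qc > qc_threshold)
  dropped <- nrow(gpp) - nrow(qualified)
  d <- dplyr::inner_join(proxies, qualified, by = c("site", "index"))
  d$era <- if (is.null(era_year)) "all" else
    ifelse(d$year < era_year, "pre", "post")

  if (!is.null(era_year)) {
    eligible <- d |>
      dplyr::distinct(.data$site, .data$era, .data$year) |>
      dplyr::count(.data$site, .data$era) |>
      tidyr::pivot_wider(names_from = "era", values_from = "n",
                         values_fill = 0L)
    keep <- eligible$site[(eligible$pre %||% 0) >= min_years &
                            (eligible$post %||% 0) >= min_years]
    d <- dplyr::filter(d, .data$site %in% keep)
  }

  sites <- d |>
    dplyr::group_by(.data$site, .data$class, .data$proxy, .data$era) |>
    dplyr::summarise(
      n_periods = sum(is.finite(.data$value) & is.finite(.data$gpp)),
      r_squared = if (sum(is.finite(.data$value) & is.finite(.data$gpp)) >= 2
                      && stats::var(.data$value, na.rm = TRUE) > 0)
        r2(.data$value, .data$gpp) else NA_real_,
      .groups = "drop")

  proxy_names <- unique(sites$proxy)
  tests <- list()
  wide <- tidyr::pivot_wider(sites, names_from = "proxy",
                             values_from = "r_squared",
                             id_cols = c("site", "class", "era"))
  for (cl in unique(wide$class)) {
    sub <- dplyr::filter(wide, .data$class == cl)
    if (nrow(sub) < 2) next
    for (i in seq_along(proxy_names)) for (j in seq_along(proxy_names)) {
      if (i >= j) next
      a <- sub[[proxy_names[i]]]; b <- sub[[proxy_names[j]]]
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) < 2) next
      if (all(a[ok] == b[ok])) {
        p2 <- 1; p1 <- 1; stat <- 0
      } else {
        tt2 <- t.test(a[ok], b[ok], paired = TRUE)
        tt1 <- t.test(a[ok], b[ok], paired = TRUE, alternative = "greater")
        p2 <- tt2$p.value; p1 <- tt1$p.value; stat <- unname(tt2$statistic)
      }
      tests[[paste(cl, i, j)]] <- tibble::tibble(
        class = cl, proxy_a = proxy_names[i], proxy_b = proxy_names[j],
        n_sites = sum(ok), mean_diff = mean(a[ok] - b[ok]), statistic = stat,
        p_two_sided = p2, p_one_sided_a_gt_b = p1,
        significant = p2 < alpha)
    }
  }
  list(sites = sites, tests = dplyr::bind_rows(tests),
       dropped_periods = dropped)
}
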