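# Cross-calibration of the harmonized drifting record against the
# reference sensor, gap-filling included.

overlap_steps <- function(drifting, reference) {
  which(apply(is.finite(reference$red), 3, any))
}

# accumulate per-center-pixel sufficient statistics of (x, y) pairs pooled
# from the (2w+1)^2 neighborhood over the given time steps
window_stats <- function(x, y, steps, half) {
  nd <- dim(x)[1:2]
  S <- list(n = matrix(0, nd[1], nd[2]), sx = matrix(0, nd[1], nd[2]),
            sy = matrix(0, nd[1], nd[2]), sxx = matrix(0, nd[1], nd[2]),
            sxy = matrix(0, nd[1], nd[2]))
  xs <- x[, , steps, drop = FALSE]
  ys <- y[, , steps, drop = FALSE]
  ok <- is.finite(xs) & is.finite(ys)
  xs[!ok] <- 0; ys[!ok] <- 0
  n2 <- apply(ok, c(1, 2), sum)
  sx2 <- apply(xs, c(1, 2), sum)
  sy2 <- apply(ys, c(1, 2), sum)
  sxx2 <- apply(xs^2, c(1, 2), sum)
  sxy2 <- apply(xs * ys, c(1, 2), sum)
  for (di in -half:half) for (dj in -half:half) {
    si <- pmin(pmax(seq_len(nd[1]) + di, 1L), nd[1])
    sj <- pmin(pmax(seq_len(nd[2]) + dj, 1L), nd[2])
    # clip at edges: out-of-grid neighbors are dropped, not reflected
    ii <- seq_len(nd[1]) + di; jj <- seq_len(nd[2]) + dj
    vi <- ii >= 1 & ii <= nd[1]; vj <- jj >= 1 & jj <= nd[2]
    w <- outer(vi, vj)
    S$n <- S$n + w * n2[si, sj]
    S$sx <- S$sx + w * sx2[si, sj]
    S$sy <- S$sy + w * sy2[si, sj]
    S$sxx <- S$sxx + w * sxx2[si, sj]
    S$sxy <- S$sxy + w * sxy2[si, sj]
  }
  S
}

stats_to_fit <- function(S, min_pairs) {
  den <- S$n * S$sxx - S$sx^2
  slope <- (S$n * S$sxy - S$sx * S$sy) / den
  intercept <- (S$sy - slope * S$sx) / S$n
  bad <- S$n < min_pairs | !is.finite(slope) | den <= 1e-12 * pmax(S$sxx, 1)
  slope[bad] <- NA_real_; intercept[bad] <- NA_real_
  list(slope = slope, intercept = intercept, n = S$n)
}

#' Fit windowed pixel-wise linear calibration maps
#'
#' For each center pixel and band, pools all co-located valid
#' (drifting, reference) pairs from the surrounding `window x window`
#' neighborhood over the overlap era and fits an OLS line mapping the
#' harmonized drifting reflectance to the reference reflectance. Fits are
#' made per period-of-year where samples allow (`per_period = TRUE`,
#' default), with a pooled all-period fallback used where they do not.
#' Sensor groups (see [sensor_epoch_table()]) are fitted separately when
#' the overlap era covers more than one group; a group without overlap
#' inherits the fitted model.
#'
#' @param drifting the harmonized drifting `refl_cube` (rho').
#' @param reference the reference `refl_cube`.
#' @param window odd window width (default 5).
#' @param per_period fit each of the 24 periods-of-year separately.
#' @param min_pairs minimum pooled pairs per fit (default 6).
#' @param epochs optional [sensor_epoch_table()] for the group split.
#' @return a `windowed_linear` object.
#' @export
fit_windowed_linear <- function(drifting, reference, window = 5,
                                per_period = TRUE, min_pairs = 6,
                                epochs = NULL) {
  check_that(window %% 2 == 1, "window must be odd")
  half <- (window - 1L) %/% 2L
  nd <- grid_dim(drifting$grid)
  ov <- overlap_steps(drifting, reference)
  check_that(length(ov) > 0, "overlap era is empty")
  time <- drifting$time

  groups <- if (is.null(epochs)) rep("all", nrow(time)) else
    epochs$group[epoch_of_year(time$year, epochs)]
  fitted_groups <- unique(groups[ov])

  fit_one <- function(band, steps) {
    pooled <- stats_to_fit(window_stats(drifting[[band]], reference[[band]],
                                        steps, half), min_pairs)
    out <- list(pooled = pooled, per_period = NULL)
    if (per_period) {
      pp <- vector("list", 24)
      for (p in 1:24) {
        sp <- steps[time$ordinal[steps] == p]
        if (length(sp) == 0) next
        pp[[p]] <- stats_to_fit(window_stats(drifting[[band]],
                                             reference[[band]], sp, half),
                                min_pairs)
      }
      out$per_period <- pp
    }
    out
  }

  models <- list()
  for (g in fitted_groups) {
    steps <- ov[groups[ov] == g]
    models[[g]] <- list(red = fit_one("red", steps),
                        nir = fit_one("nir", steps))
  }
  structure(list(models = models, window = window, per_period = per_period,
                 min_pairs = min_pairs, fitted_groups = fitted_groups,
                 groups = groups),
            class = "windowed_linear")
}

# coefficient lookup for one band/time step; falls back per-period -> pooled
lin_coef_for <- function(lin, group, band, ordinal) {
  m <- lin$models[[group]] %||% lin$models[[lin$fitted_groups[1]]]
  b <- m[[band]]
  if (!is.null(b$per_period) && !is.null(b$per_period[[ordinal]])) {
    pp <- b$per_period[[ordinal]]
    slope <- pp$slope; intercept <- pp$intercept
    use_pool <- !is.finite(slope)
    slope[use_pool] <- b$pooled$slope[use_pool]
    intercept[use_pool] <- b$pooled$intercept[use_pool]
    list(slope = slope, intercept = intercept)
  } else {
    list(slope = b$pooled$slope, intercept = b$pooled$intercept)
  }
}

#' Apply the windowed linear calibration to a cube
#'
#' Pixels with no fitted model (per-period or pooled) pass through
#' unchanged; their count is attached as attribute `"passthrough"`.
#'
#' @param cube a `refl_cube` (the harmonized drifting stream).
#' @param lin a [fit_windowed_linear()] model.
#' @return the linearly calibrated cube.
#' @export
apply_windowed_linear <- function(cube, lin) {
  nd <- grid_dim(cube$grid); nt <- nrow(cube$time)
  out <- cube
  passthrough <- 0L
  for (band in c("red", "nir")) {
    a <- cube[[band]]
    res <- a
    for (k in seq_len(nt)) {
      cf <- lin_coef_for(lin, lin$groups[k], band, cube$time$ordinal[k])
      v <- cf$slope * a[, , k] + cf$intercept
      keep_raw <- !is.finite(cf$slope) & is.finite(a[, , k])
      passthrough <- passthrough + sum(keep_raw)
      v[keep_raw] <- a[, , k][keep_raw]
      res[, , k] <- v
    }
    out[[band]] <- res
  }
  attr(out, "passthrough") <- passthrough
  out
}

#' Residual between the reference and the linearly corrected record
#'
#' @param linear_corrected output of [apply_windowed_linear()].
#' @param reference the reference `refl_cube`.
#' @return a list with `gamma_red`/`gamma_nir` arrays (NaN where either
#'   side is missing), the grid and time table.
#' @export
compute_residual <- function(linear_corrected, reference) {
  list(gamma_red = reference$red - linear_corrected$red,
       gamma_nir = reference$nir - linear_corrected$nir,
       grid = linear_corrected$grid, time = linear_corrected$time)
}

residual_features <- function(met, corrected, steps) {
  nd <- grid_dim(met$grid); npix <- prod(nd)
  f3 <- function(a) as.vector(a[, , steps, drop = FALSE])
  fs <- function(m) rep(as.vector(m), length(steps))
  cbind(aod = f3(met$aod), sd = f3(met$sd), cc = f3(met$cc),
        ele = fs(met$ele), ai = fs(met$ai),
        red = f3(corrected$red), nir = f3(corrected$nir))
}

#' Train the residual network on environmental covariates
#'
#' A small feedforward network maps (AOD, snow depth, cloud cover,
#' elevation, aridity index, linearly corrected red and NIR) to the
#' remaining residual per band. Geographic coordinates are deliberately
#' not predictors. Validation is split off by period blocks (every fourth
#' overlap period) to respect temporal structure; rows with non-finite
#' features or targets are dropped with a count recorded.
#'
#' @param gamma a [compute_residual()] result.
#' @param met the `met_cube`.
#' @param corrected the linearly corrected cube (feature source).
#' @param hidden hidden layer sizes (default one layer of 32 units).
#' @param epochs training epochs (full-batch Adam steps; default 400).
#' @param lr learning rate.
#' @param max_samples cap on training rows (seeded subsample).
#' @param per_period train 24 separate period-of-year models instead of
#'   one pooled model.
#' @param seed integer seed.
#' @return a `residual_model` with the network(s), the feature order and
#'   validation RMSE/R2 per band.
#' @export
train_residual_model <- function(gamma, met, corrected, hidden = 32,
                                 epochs = 400, lr = 0.01,
                                 max_samples = 100000, per_period = FALSE,
                                 seed = 1) {
  steps <- which(apply(is.finite(gamma$gamma_red), 3, any))
  check_that(length(steps) > 0, "no overlap residuals to train on")
  val_steps <- steps[seq_along(steps) %% 4L == 0L]
  if (length(val_steps) == 0) val_steps <- steps[length(steps)]
  tr_steps <- setdiff(steps, val_steps)

  build <- function(ss) {
    x <- residual_features(met, corrected, ss)
    y <- cbind(red = as.vector(gamma$gamma_red[, , ss, drop = FALSE]),
               nir = as.vector(gamma$gamma_nir[, , ss, drop = FALSE]))
    ok <- complete.cases(x) & complete.cases(y) &
      rowSums(!is.finite(x)) == 0 & rowSums(!is.finite(y)) == 0
    list(x = x[ok, , drop = FALSE], y = y[ok, , drop = FALSE],
         dropped = sum(!ok))
  }
  tr <- build(tr_steps); va <- build(val_steps)
  if (nrow(tr$x) > max_samples) {
    keep <- with_seed(seed, sample.int(nrow(tr$x), max_samples))
    tr$x <- tr$x[keep, , drop = FALSE]; tr$y <- tr$y[keep, , drop = FALSE]
  }

  fit <- function(x, y) mlp_fit(x, y, hidden = hidden, lr = lr,
                                epochs = epochs, batch_size = Inf,
                                seed = seed)
  if (per_period) {
    time <- gamma$time
    nets <- vector("list", 24)
    for (p in 1:24) {
      sp <- tr_steps[time$ordinal[tr_steps] == p]
      if (length(sp) == 0) next
      d <- build(sp)
      if (nrow(d$x) >= 10) nets[[p]] <- fit(d$x, d$y)
    }
    pooled <- fit(tr$x, tr$y)
    model <- list(per_period = nets, pooled = pooled)
    pv <- mlp_predict(pooled, va$x)
  } else {
    pooled <- fit(tr$x, tr$y)
    model <- list(per_period = NULL, pooled = pooled)
    pv <- mlp_predict(pooled, va$x)
  }
  pv <- as.matrix(pv)
  val <- tibble::tibble(
    band = c("red", "nir"),
    rmse = c(rmse(pv[, 1], va$y[, 1]), rmse(pv[, 2], va$y[, 2])),
    r2 = c(r2(pv[, 1], va$y[, 1]), r2(pv[, 2], va$y[, 2])))
  structure(list(model = model, features = colnames(tr$x),
                 validation = val, dropped_rows = tr$dropped + va$dropped,
                 per_period = per_period),
            class = "residual_model")
}

# predict gamma for given steps -> list(red, nir) arrays
predict_residual <- function(res, met, corrected, steps = NULL) {
  time <- corrected$time
  nd <- grid_dim(corrected$grid)
  if (is.null(steps)) steps <- seq_len(nrow(time))
  x <- residual_features(met, corrected, steps)
  net_for <- function(p) {
    if (res$per_period && !is.null(res$model$per_period[[p]]))
      res$model$per_period[[p]] else res$model$pooled
  }
  if (res$per_period) {
    pred <- matrix(NA_real_, nrow(x), 2)
    rows_per_step <- prod(nd)
    for (i in seq_along(steps)) {
      rows <- (i - 1L) * rows_per_step + seq_len(rows_per_step)
      pred[rows, ] <- as.matrix(mlp_predict(net_for(time$ordinal[steps[i]]),
                                            x[rows, , drop = FALSE]))
    }
  } else {
    pred <- as.matrix(mlp_predict(res$model$pooled, x))
  }
  list(red = array(pred[, 1], c(nd, length(steps))),
       nir = array(pred[, 2], c(nd, length(steps))))
}

#' Apply the full double calibration
#'
#' Linear map plus residual-network correction, over the whole record
#' including eras with no reference data: `calibrated = lin(rho') +
#' f(covariates, lin(rho'))`.
#'
#' @param drifting the harmonized drifting cube (rho').
#' @param lin a [fit_windowed_linear()] model.
#' @param res a [train_residual_model()] model (or `NULL` for linear-only).
#' @param met the `met_cube` (must cover all target periods).
#' @return the calibrated `refl_cube`.
#' @export
apply_double_calibration <- function(drifting, lin, res, met) {
  out <- apply_windowed_linear(drifting, lin)
  if (!is.null(res)) {
    g <- predict_residual(res, met, out)
    out$red <- out$red + g$red
    out$nir <- out$nir + g$nir
  }
  out
}

#' Fill missing periods with the adjacent-year seasonal mean
#'
#' Each missing pixel-period is filled with the mean of the same
#' period-of-year in the preceding and following year (one-sided at record
#' edges). Fill provenance is recorded per band in `fill_<band>` integer
#' arrays: 0 observed, 1 seasonal-filled, 3 still missing.
#'
#' @param cube a biweekly `refl_cube`.
#' @return the filled cube with provenance arrays added.
#' @export
seasonal_mean_fill <- function(cube) {
  nt <- nrow(cube$time)
  out <- cube
  for (band in c("red", "nir")) {
    a <- cube[[band]]
    filled <- a
    prov <- array(0L, dim(a))
    prov[!is.finite(a)] <- 3L
    for (k in seq_len(nt)) {
      prev <- k - 24L; nxt <- k + 24L
      cand <- c(if (prev >= 1) prev, if (nxt <= nt) nxt)
      if (length(cand) == 0) next
      gap <- !is.finite(a[, , k])
      if (!any(gap)) next
      neigh <- a[, , cand, drop = FALSE]
      m <- apply(neigh, c(1, 2), function(v) {
        v <- v[is.finite(v)]
        if (length(v)) mean(v) else NA_real_
      })
      fill <- gap & is.finite(m)
      slice <- filled[, , k]; slice[fill] <- m[fill]
      filled[, , k] <- slice
      pslice <- prov[, , k]; pslice[fill] <- 1L
      prov[, , k] <- pslice
    }
    out[[band]] <- filled
    out[[paste0("fill_", band)]] <- prov
  }
  out
}

#' Harmonic analysis of time series (HANTS) fit for one series
#'
#' Iterative least-squares fit of a mean plus `n_harmonics` harmonics of
#' the annual cycle (24-period base). At each iteration, points whose
#' residual is below `-threshold * sd(residuals)` are rejected
#' (low-side rejection, appropriate for reflectance/VI-type series whose
#' outliers are cloud-contaminated low values); the loop stops when no
#' point is rejected, `max_iter` is reached, or fewer than `min_points`
#' points remain.
#'
#' @param y numeric series (NA/NaN = missing).
#' @param ordinal period-of-year (1-24) per element.
#' @param n_harmonics number of harmonics (>= 1, default 3).
#' @param threshold rejection threshold in residual-sd units (default 2.5).
#' @param max_iter maximum rejection iterations (default 10).
#' @param min_points minimum retained points (default `2*n_harmonics + 1`).
#' @param two_sided reject on both sides instead of low-only.
#' @return list with `fitted` (full-length harmonic curve), `filled`
#'   (observed values kept, gaps replaced by the curve), `used` (logical:
#'   point retained in the final fit), `converged`, `iterations`.
#' @export
hants_fit <- function(y, ordinal, n_harmonics = 3, threshold = 2.5,
                      max_iter = 10, min_points = 2 * n_harmonics + 1,
                      two_sided = FALSE) {
  check_that(n_harmonics >= 1, "n_harmonics must be >= 1")
  check_that(threshold > 0, "threshold must be positive")
  n <- length(y)
  ang <- 2 * pi * ordinal / 24
  X <- cbind(1, do.call(cbind, lapply(seq_len(n_harmonics), function(h)
    cbind(cos(h * ang), sin(h * ang)))))
  use <- is.finite(y)
  if (sum(use) < max(min_points, ncol(X))) {
    return(list(fitted = rep(NA_real_, n), filled = y, used = use,
                converged = FALSE, iterations = 0L))
  }
  it <- 0L
  repeat {
    fit <- stats::lm.fit(X[use, , drop = FALSE], y[use])
    curve <- as.vector(X %*% fit$coefficients)
    resid <- y - curve
    s <- sd(resid[use])
    it <- it + 1L
    # an essentially exact fit has converged; avoids chattering on the
    # +/- eps residuals of noiseless harmonic data
    if (!is.finite(s) || s < 1e-10 || it >= max_iter) break
    bad <- if (two_sided) abs(resid) > threshold * s else
      resid < -threshold * s
    bad <- bad & use
    if (!any(bad, na.rm = TRUE)) break
    if (sum(use) - sum(bad, na.rm = TRUE) < max(min_points, ncol(X))) break
    use <- use & !bad
  }
  filled <- y
  filled[!is.finite(y)] <- curve[!is.finite(y)]
  list(fitted = curve, filled = filled, used = use, converged = TRUE,
       iterations = it)
}

#' HANTS gap-filling of a reflectance cube
#'
#' Applies [hants_fit()] per pixel and band to the remaining gaps after
#' [seasonal_mean_fill()]. Observed (and seasonally filled) values are
#' never altered; provenance arrays are updated (2 = HANTS-filled).
#'
#' @param cube a `refl_cube`, typically after [seasonal_mean_fill()].
#' @param ... arguments passed to [hants_fit()].
#' @return the gap-filled cube.
#' @export
hants_gapfill <- function(cube, ...) {
  nd <- grid_dim(cube$grid); npix <- prod(nd); nt <- nrow(cube$time)
  ord <- cube$time$ordinal
  out <- cube
  for (band in c("red", "nir")) {
    a <- matrix(cube[[band]], npix, nt)
    prov <- out[[paste0("fill_", band)]]
    if (is.null(prov)) {
      prov <- array(0L, c(nd, nt))
      prov[!is.finite(cube[[band]])] <- 3L
    }
    pm <- matrix(prov, npix, nt)
    for (i in seq_len(npix)) {
      yi <- a[i, ]
      if (all(is.finite(yi))) next
      h <- hants_fit(yi, ord, ...)
      gap <- !is.finite(yi) & is.finite(h$filled)
      a[i, gap] <- h$filled[gap]
      pm[i, gap] <- 2L
    }
    out[[band]] <- array(a, c(nd, nt))
    out[[paste0("fill_", band)]] <- array(pm, c(nd, nt))
  }
  out
}
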