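# Windowed linear calibration, residual network, double calibration and
# gap filling.

# a pair of cubes where drifting = (reference - c)/m exactly
affine_pair <- function(m = 1.2, c = 0.05, nlat = 6, nlon = 6,
                        years = c(1994, 1997), seed = 1) {
  g <- grid_spec(nlat, nlon)
  truth <- surface_truth_model(g, n_pics = 2, seed = seed)
  tm <- biweekly_seq(years[1], years[2])
  tr <- lcspp:::truth_reflectance(truth, tm)
  nt <- nrow(tm); nd <- c(nlat, nlon)
  mk <- function(a) new_cube(g, tm, red = a$red, nir = a$nir,
                             sza = array(45, c(nd, nt)),
                             qc = array(0L, c(nd, nt)),
                             sensor_id = rep("X", nt), class = "refl_cube")
  reference <- mk(tr)
  drifting <- mk(list(red = (tr$red - c) / m, nir = (tr$nir - c) / m))
  list(drifting = drifting, reference = reference, grid = g, truth = truth)
}

test_that("a noiseless affine map is inverted to numerical precision", {
  p <- affine_pair(m = 1.2, c = 0.05)
  lin <- fit_windowed_linear(p$drifting, p$reference, per_period = FALSE)
  mod <- lin$models$all$red$pooled
  expect_lt(max(abs(mod$slope - 1.2), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(mod$intercept - 0.05), na.rm = TRUE), 1e-6)
  corrected <- apply_windowed_linear(p$drifting, lin)
  expect_lt(max(abs(corrected$red - p$reference$red), na.rm = TRUE), 1e-8)
  gam <- compute_residual(corrected, p$reference)
  expect_lt(max(abs(gam$gamma_red), na.rm = TRUE), 1e-8)
})

test_that("identity data give slope 1, intercept 0, even at clipped edges", {
  p <- affine_pair(m = 1, c = 0)
  lin <- fit_windowed_linear(p$drifting, p$reference, per_period = FALSE)
  mod <- lin$models$all$red$pooled
  expect_lt(max(abs(mod$slope - 1)), 1e-8)
  expect_lt(max(abs(mod$intercept)), 1e-8)
  # corner pixels pooled from the clipped 3x3 neighborhood still fit
  expect_true(is.finite(mod$slope[1, 1]))
  expect_gte(mod$n[1, 1], 6)
  expect_lt(mod$n[1, 1], mod$n[3, 3])   # fewer pairs at the corner
})

test_that("pixels with too few or degenerate pairs are flagged unfitted", {
  p <- affine_pair()
  # constant predictor at one pixel: slope undefined
  p$drifting$red[2, 2, ] <- 0.2
  lin <- fit_windowed_linear(p$drifting, p$reference, window = 1,
                             per_period = FALSE)
  expect_true(is.na(lin$models$all$red$pooled$slope[2, 2]))
  # too few pairs
  p2 <- affine_pair()
  p2$drifting$red[3, 3, ] <- NaN
  p2$drifting$red[3, 3, 1:4] <- 0.2 + (1:4) / 100
  lin2 <- fit_windowed_linear(p2$drifting, p2$reference, window = 1,
                              per_period = FALSE, min_pairs = 6)
  expect_true(is.na(lin2$models$all$red$pooled$slope[3, 3]))
  # pass-through on application
  out <- apply_windowed_linear(p2$drifting, lin2)
  expect_gt(attr(out, "passthrough"), 0)
  expect_equal(out$red[3, 3, 2], p2$drifting$red[3, 3, 2])
})

test_that("residuals average to ~0 when the linear fit has an intercept", {
  set.seed(2)
  p <- affine_pair(m = 1.1, c = 0.02)
  noisy <- p$drifting
  noisy$red <- noisy$red + array(rnorm(length(noisy$red), 0, 0.01),
                                 dim(noisy$red))
  lin <- fit_windowed_linear(noisy, p$reference, per_period = FALSE)
  corrected <- apply_windowed_linear(noisy, lin)
  gam <- compute_residual(corrected, p$reference)
  # OLS orthogonality: pooled residual mean near zero
  expect_lt(abs(mean(gam$gamma_red, na.rm = TRUE)), 2e-4)
  # a constant reference shift propagates into gamma exactly
  shifted <- p$reference
  shifted$red <- shifted$red + 0.01
  gam2 <- compute_residual(corrected, shifted)
  expect_equal(gam2$gamma_red, gam$gamma_red + 0.01, tolerance = 1e-12)
})

test_that("the residual network recovers a covariate-driven residual", {
  g <- grid_spec(8, 8)
  tm <- biweekly_seq(1994, 1996)
  met <- simulate_covariates(g, tm, seed = 3)
  nd <- grid_dim(g); nt <- nrow(tm)
  base <- array(0.2, c(nd, nt))
  corrected <- new_cube(g, tm, red = base, nir = base + 0.2,
                        sza = array(45, c(nd, nt)),
                        qc = array(0L, c(nd, nt)),
                        sensor_id = rep("X", nt), class = "refl_cube")
  # gamma is a noiseless linear function of AOD
  gam <- list(gamma_red = 0.05 * met$aod, gamma_nir = -0.03 * met$aod,
              grid = g, time = tm)
  res <- train_residual_model(gam, met, corrected, epochs = 800, seed = 4)
  expect_gt(res$validation$r2[1], 0.99)
  expect_gt(res$validation$r2[2], 0.99)

  # null target -> null prediction
  gam0 <- list(gamma_red = base * 0, gamma_nir = base * 0, grid = g, time = tm)
  res0 <- train_residual_model(gam0, met, corrected, epochs = 600, seed = 5)
  pred <- lcspp:::predict_residual(res0, met, corrected)
  expect_lt(abs(mean(pred$red)), 1e-3)

  # permuting features against targets destroys the fit
  met_perm <- met
  perm <- sample(nt)
  for (f in c("aod", "sd", "cc", "ta", "p", "rad"))
    met_perm[[f]] <- met[[f]][, , perm]
  res_perm <- train_residual_model(gam, met_perm, corrected, epochs = 400,
                                   seed = 6)
  expect_lt(res_perm$validation$r2[1], 0.2)
})

test_that("double calibration composes and improves monotonically", {
  # drifting = affine(reference) + covariate-driven residual
  g <- grid_spec(8, 8)
  truth <- surface_truth_model(g, n_pics = 2, seed = 7)
  tm <- biweekly_seq(1994, 1997)
  tr <- lcspp:::truth_reflectance(truth, tm)
  met <- simulate_covariates(g, tm, seed = 8)
  nd <- grid_dim(g); nt <- nrow(tm)
  set.seed(9)
  ref_red <- tr$red; ref_nir <- tr$nir
  drift_red <- (tr$red - 0.04 - 0.04 * met$aod) / 1.1
  drift_nir <- (tr$nir - 0.02 - 0.05 * met$aod) / 0.95
  mk <- function(r, n, noise = 0) {
    new_cube(g, tm, red = r + rnorm(length(r), 0, noise),
             nir = n + rnorm(length(n), 0, noise),
             sza = array(45, c(nd, nt)), qc = array(0L, c(nd, nt)),
             sensor_id = rep("X", nt), class = "refl_cube")
  }
  reference <- mk(ref_red, ref_nir)
  drifting <- mk(drift_red, drift_nir, noise = 0.002)
  lin <- fit_windowed_linear(drifting, reference, per_period = FALSE)
  linear_only <- apply_windowed_linear(drifting, lin)
  gam <- compute_residual(linear_only, reference)
  res <- train_residual_model(gam, met, linear_only, epochs = 800, seed = 10)
  calibrated <- apply_double_calibration(drifting, lin, res, met)

  r <- function(cube) rmse(as.vector(cube$red), as.vector(reference$red))
  expect_lt(r(calibrated), r(linear_only))
  expect_lt(r(linear_only), r(drifting))

  # with the residual predicted exactly, calibrated == reference
  exact <- linear_only
  exact$red <- linear_only$red + gam$gamma_red
  exact$nir <- linear_only$nir + gam$gamma_nir
  expect_equal(exact$red, reference$red, tolerance = 1e-10)
})

test_that("seasonal mean fill uses adjacent-year neighbors, one-sided at edges", {
  cube <- tiny_cube(nlat = 1, nlon = 1, years = c(1993, 1995))
  cube$red[1, 1, ] <- rep(c(0.3, 0.4, 0.5), each = 24)
  k94 <- which(cube$time$year == 1994 & cube$time$ordinal == 10)
  k93 <- which(cube$time$year == 1993 & cube$time$ordinal == 3)
  cube$red[1, 1, c(k93, k94)] <- NaN
  out <- seasonal_mean_fill(cube)
  expect_equal(out$red[1, 1, k94], 0.4)       # mean(0.3, 0.5)
  expect_equal(out$red[1, 1, k93], 0.4)       # one-sided: next year only
  expect_equal(out$fill_red[1, 1, k94], 1L)
  # no other values were touched
  expect_equal(out$red[1, 1, -c(k93, k94)], cube$red[1, 1, -c(k93, k94)])
  # no gaps -> identity
  out2 <- seasonal_mean_fill(out)
  expect_equal(out2$red, out$red)
})

test_that("HANTS recovers harmonics exactly and rejects low outliers", {
  tm <- biweekly_seq(1990, 1993)
  ord <- tm$ordinal
  t <- seq_len(nrow(tm))
  truth <- 0.4 + 0.1 * cos(2 * pi * ord / 24 - 1) +
    0.05 * sin(4 * pi * ord / 24 + 0.5)
  set.seed(11)
  y <- truth
  deleted <- sample(length(y), round(0.3 * length(y)))
  y[deleted] <- NA
  fit <- hants_fit(y, ord, n_harmonics = 3)
  expect_lt(max(abs(fit$filled[deleted] - truth[deleted])), 1e-8)
  expect_equal(fit$filled[-deleted], truth[-deleted])  # observed kept

  # constant series
  cfit <- hants_fit(rep(0.25, 48), ord[1:48])
  expect_equal(unique(round(cfit$fitted, 12)), 0.25)

  # one large negative outlier: rejected, fit unchanged to 1e-6
  y2 <- truth
  y2[20] <- truth[20] - 0.4
  fit2 <- hants_fit(y2, ord, n_harmonics = 3)
  expect_false(fit2$used[20])
  expect_lte(fit2$iterations, 2L)
  expect_lt(max(abs(fit2$fitted - truth)), 1e-6)

  # insufficient points -> unfilled, flagged
  y3 <- rep(NA_real_, 96); y3[1:5] <- 0.3
  fit3 <- hants_fit(y3, ord, n_harmonics = 3)
  expect_false(fit3$converged)
})

test_that("cube-level gap filling partitions provenance exactly", {
  sc <- small_scene(nlat = 5, nlon = 5, gap_prob = 0.15)
  filled <- hants_gapfill(seasonal_mean_fill(sc$drifting))
  prov <- filled$fill_red
  obs <- is.finite(sc$drifting$red)
  expect_true(all(prov[obs] == 0L))
  expect_true(all(prov[!obs] %in% c(1L, 2L, 3L)))
  # observed values never altered
  expect_equal(filled$red[obs], sc$drifting$red[obs])
  # everything flagged 1 or 2 is now finite
  expect_true(all(is.finite(filled$red[prov == 1L | prov == 2L])))
})
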