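# PICS bias proxy and the SZA/inter-sensor-bias regression (the
# harmonization stage), including exact parameter recovery on constructed
# data.

two_epochs <- function() {
  sensor_epoch_table(1990, c(4, 4), sensor_id = c("N07", "MetOpB"),
                     group = c("noaa", "metop"))
}

test_that("delta is zero when the drifting epoch matches the reference truth", {
  g <- grid_spec(6, 6)
  truth <- surface_truth_model(g, n_pics = 4, seed = 1)
  ep <- two_epochs()
  inj <- artifact_injection(ep, drift_max = c(N07 = 0, MetOpB = 0),
                            delta_red = c(N07 = 0, MetOpB = 0),
                            delta_nir = c(N07 = 0, MetOpB = 0),
                            a1_red = 0, a1_nir = 0,
                            met_coef = c(ta = 0, p = 0, rad = 0),
                            noise_sd = 0, gap_prob = 0)
  sc <- simulate_scene(truth, inj, ep, seed = 2)
  pb <- compute_pics_bias(sc$drifting, truth$pics_idx, ep)
  expect_equal(max(abs(pb$series$delta_red)), 0, tolerance = 1e-12)
  expect_equal(max(abs(pb$series$delta_nir)), 0, tolerance = 1e-12)
})

test_that("a flat injected offset is recovered exactly without noise", {
  g <- grid_spec(6, 6)
  truth <- surface_truth_model(g, n_pics = 4, seed = 3)
  ep <- two_epochs()
  inj <- artifact_injection(ep, drift_max = c(N07 = 0, MetOpB = 0),
                            delta_red = c(N07 = 0.02, MetOpB = 0),
                            delta_nir = c(N07 = 0.015, MetOpB = 0),
                            a1_red = 0, a1_nir = 0,
                            met_coef = c(ta = 0, p = 0, rad = 0),
                            noise_sd = 0, gap_prob = 0)
  sc <- simulate_scene(truth, inj, ep, seed = 4)
  pb <- compute_pics_bias(sc$drifting, truth$pics_idx, ep)
  ep1 <- pb$series$year <= 1993
  expect_equal(unique(round(pb$series$delta_red[ep1], 10)), 0.02)
  expect_equal(unique(round(pb$series$delta_nir[ep1], 10)), 0.015)
  expect_equal(max(abs(pb$series$delta_red[!ep1])), 0, tolerance = 1e-12)
})

test_that("delta noise scales as sigma/sqrt(k) over PICS pixels", {
  g <- grid_spec(10, 10)
  truth <- surface_truth_model(g, n_pics = 16, seed = 5)
  ep <- two_epochs()
  sigma <- 0.01
  inj <- artifact_injection(ep, drift_max = c(N07 = 0, MetOpB = 0),
                            delta_red = c(N07 = 0, MetOpB = 0),
                            delta_nir = c(N07 = 0, MetOpB = 0),
                            a1_red = 0, a1_nir = 0,
                            met_coef = c(ta = 0, p = 0, rad = 0),
                            noise_sd = sigma, gap_prob = 0)
  sc <- simulate_scene(truth, inj, ep, seed = 6)
  pb <- compute_pics_bias(sc$drifting, truth$pics_idx, ep)
  ep1 <- pb$series$year <= 1993
  # drifting-epoch delta = PICS noise mean (k pixels) minus MSC noise
  k <- length(truth$pics_idx)
  years_ref <- 4
  expected_sd <- sigma * sqrt(1 / k + 1 / (k * years_ref))
  expect_equal(sd(pb$series$delta_red[ep1]), expected_sd, tolerance = 0.25)
})

test_that("a period-of-year never seen in the reference epoch is an error", {
  g <- grid_spec(3, 3)
  truth <- surface_truth_model(g, n_pics = 2, seed = 7)
  ep <- two_epochs()
  inj <- artifact_injection(ep, drift_max = c(N07 = 0, MetOpB = 0),
                            delta_red = c(N07 = 0, MetOpB = 0),
                            delta_nir = c(N07 = 0, MetOpB = 0), gap_prob = 0)
  sc <- simulate_scene(truth, inj, ep, seed = 8)
  ref <- sc$drifting$time$year >= 1994
  sc$drifting$red[, , ref & sc$drifting$time$ordinal == 5] <- NaN
  expect_error(compute_pics_bias(sc$drifting, truth$pics_idx, ep),
               "period-of-year: 5", class = "lcspp_data_error")
})

test_that("noiseless linear construction recovers all six coefficients", {
  # build a record exactly from the regression equation with known
  # coefficients, then check recovery to numerical precision
  g <- grid_spec(4, 4)
  nd <- grid_dim(g); npix <- prod(nd)
  tm <- biweekly_seq(1982, 1993)   # 12 years
  nt <- nrow(tm)
  set.seed(9)
  met <- simulate_covariates(g, tm, seed = 10)
  sza <- array(rep(45, npix * nt), c(nd, nt)) +
    array(rep(sin(seq_len(nt) / 7), each = npix), c(nd, nt))
  truth_coef <- list(a1 = 0.002, a2 = 0.8, a3 = 3e-4, a4 = -6e-5,
                     a5 = 2e-5, b = 0.25)
  delta_series <- rep(c(0.03, 0.01, 0), times = c(nt / 3, nt / 3, nt / 3))
  ord <- tm$ordinal
  anom <- function(a) a - lcspp:::clim_expand(lcspp:::clim_mean_fast(a, ord), ord)
  sza_a <- anom(sza); ta_a <- anom(met$ta); p_a <- anom(met$p)
  rad_a <- anom(met$rad)
  rho <- truth_coef$b + truth_coef$a1 * sza_a +
    array(rep(truth_coef$a2 * delta_series, each = npix), c(nd, nt)) +
    truth_coef$a3 * ta_a + truth_coef$a4 * p_a + truth_coef$a5 * rad_a
  ep <- two_epochs()
  cube <- new_cube(g, tm, red = rho, nir = rho, sza = sza,
                   qc = array(0L, c(nd, nt)),
                   sensor_id = rep("N07", nt), class = "refl_cube")
  pb <- list(series = tibble::tibble(index = tm$index, year = tm$year,
                                     ordinal = ord,
                                     delta_red = delta_series,
                                     delta_nir = delta_series))
  model <- fit_sza_bias_model(cube, pb, met, min_n = 8)
  expect_lt(max(abs(model$coef_red[, , 1] - truth_coef$a1), na.rm = TRUE), 1e-8)
  expect_lt(max(abs(model$coef_red[, , 2] - truth_coef$a2), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(model$coef_red[, , 3] - truth_coef$a3), na.rm = TRUE), 1e-8)
  expect_lt(max(abs(model$coef_red[, , 4] - truth_coef$a4), na.rm = TRUE), 1e-8)
  expect_lt(max(abs(model$coef_red[, , 5] - truth_coef$a5), na.rm = TRUE), 1e-8)

  # removal takes the record back to the retained (met + intercept) part
  corrected <- remove_sza_bias(cube, model, pb, ep)
  retained <- truth_coef$b + truth_coef$a3 * ta_a + truth_coef$a4 * p_a +
    truth_coef$a5 * rad_a
  idx_nonref <- which(tm$year < 1994)   # drifting epoch only
  err <- corrected$red[, , idx_nonref] - retained[, , idx_nonref]
  expect_lt(max(abs(err)), 1e-6)
})

test_that("zero SZA signal yields a1 indistinguishable from zero", {
  g <- grid_spec(5, 5)
  truth <- surface_truth_model(g, n_pics = 4, seed = 11)
  ep <- two_epochs()
  inj <- artifact_injection(ep, drift_max = c(N07 = 0, MetOpB = 0),
                            delta_red = c(N07 = 0.02, MetOpB = 0),
                            delta_nir = c(N07 = 0.02, MetOpB = 0),
                            a1_red = 0, a1_nir = 0, noise_sd = 0.005,
                            gap_prob = 0)
  sc <- simulate_scene(truth, inj, ep, seed = 12)
  # add independent per-composite SZA jitter so a1 is estimable but null
  set.seed(13)
  sc$drifting$sza <- sc$drifting$sza +
    array(rnorm(length(sc$drifting$sza), 0, 2), dim(sc$drifting$sza))
  pb <- compute_pics_bias(sc$drifting, truth$pics_idx, ep)
  model <- fit_sza_bias_model(sc$drifting, pb, sc$met)
  a1 <- model$coef_red[, , 1]
  expect_lt(abs(median(a1, na.rm = TRUE)), 3 * sd(a1, na.rm = TRUE))
})

test_that("pixels with too few periods are left unfitted and pass through", {
  g <- grid_spec(3, 3)
  truth <- surface_truth_model(g, n_pics = 2, seed = 14)
  ep <- two_epochs()
  inj <- artifact_injection(ep, drift_max = c(N07 = 5, MetOpB = 0),
                            delta_red = c(N07 = 0.02, MetOpB = 0),
                            delta_nir = c(N07 = 0.02, MetOpB = 0),
                            gap_prob = 0)
  sc <- simulate_scene(truth, inj, ep, seed = 15)
  # knock out pixel 1 at period 1 in all but 3 years
  m <- matrix(sc$drifting$red, 9, nrow(sc$drifting$time))
  kill <- which(sc$drifting$time$ordinal == 1)[1:3]   # 1990-1992
  m[1, kill] <- NaN
  sc$drifting$red <- array(m, dim(sc$drifting$red))
  pb <- compute_pics_bias(sc$drifting, truth$pics_idx, ep)
  model <- fit_sza_bias_model(sc$drifting, pb, sc$met, min_n = 8)
  expect_true(is.na(model$coef_red[1, 1, 1]))
  expect_equal(model$n[1, 1], 5L)
  corrected <- remove_sza_bias(sc$drifting, model, pb, ep)
  expect_gt(attr(corrected, "unfitted"), 0)
  # the unfitted pixel-period passes through unchanged
  k <- which(sc$drifting$time$ordinal == 1 & sc$drifting$time$year == 1993)
  expect_equal(corrected$red[1, 1, k], sc$drifting$red[1, 1, k])
})

test_that("correction never touches the reference epoch and is idempotent", {
  sc <- small_scene(nlat = 8, nlon = 8)
  ps <- pics_sets(sc$truth)
  pb <- compute_pics_bias(sc$drifting, ps$calibration, sc$epochs)
  model <- fit_sza_bias_model(sc$drifting, pb, sc$met)
  corrected <- remove_sza_bias(sc$drifting, model, pb, sc$epochs)
  ref <- sc$drifting$time$year >= 1992
  expect_identical(corrected$red[, , ref], sc$drifting$red[, , ref])

  # refitting on corrected data: removable coefficients shrink strongly
  pb2 <- compute_pics_bias(corrected, ps$calibration, sc$epochs)
  model2 <- fit_sza_bias_model(corrected, pb2, sc$met)
  corrected2 <- remove_sza_bias(corrected, model2, pb2, sc$epochs)
  d1 <- mean(abs(corrected$red - sc$drifting$red), na.rm = TRUE)
  d2 <- mean(abs(corrected2$red - corrected$red), na.rm = TRUE)
  expect_lt(d2, 0.35 * d1)
})
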