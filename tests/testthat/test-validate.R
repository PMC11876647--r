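# Vegetation indices, accuracy metrics, PICS diagnostics, trends, masks
# and the site-level GPP comparison.

test_that("vegetation indices match hand arithmetic and the kNDVI identity", {
  vi <- vegetation_indices(0.05, 0.45, rad = 200)
  expect_equal(vi$ndvi, 0.8)
  expect_equal(vi$nirv, 0.36)
  expect_equal(vi$nirvp, 72)
  # default sigma = 0.5(nir+red): kNDVI == tanh(NDVI^2) identically
  set.seed(1)
  red <- runif(200, 0.01, 0.3); nir <- runif(200, 0.1, 0.6)
  vi2 <- vegetation_indices(red, nir)
  expect_equal(vi2$kndvi, tanh(vi2$ndvi^2), tolerance = 1e-12)
  # zero contrast and explicit sigma
  vi0 <- vegetation_indices(0.2, 0.2)
  expect_equal(unlist(vi0[1, ]), c(ndvi = 0, kndvi = 0, nirv = 0))
  vi3 <- vegetation_indices(0.1, 0.3, sigma = 0.1)
  expect_equal(vi3$kndvi, tanh(1))
  # undefined at nir + red = 0
  expect_true(is.na(vegetation_indices(0, 0)$ndvi))
})

test_that("accuracy metrics agree with hand computations", {
  expect_equal(nse(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(r2(c(1, 2, 3), c(2, 4, 6)), 1)
  # climatology baseline: NSE exactly 0
  obs <- c(1, 2, 3)
  expect_equal(nse(rep(mean(obs), 3), obs), 0)
  expect_equal(rmse(c(2, 2, 2), obs), sqrt(2 / 3))
  expect_equal(nse(c(2, 2, 2), obs), 0)
  expect_error(nse(c(1, 2), c(5, 5)), "zero variance")
  expect_error(nse(1, 1))
})

test_that("pics diagnostics recover constructed steps and stay 0 when flat", {
  g <- grid_spec(4, 4)
  tm <- biweekly_seq(1982, 1989)
  nd <- c(4, 4); nt <- nrow(tm)
  ep <- sensor_epoch_table(1982, c(4, 4), sensor_id = c("A", "B"),
                          group = c("noaa", "metop"))
  base <- array(0.4, c(nd, nt))
  mk <- function(a) new_cube(g, tm, red = a, nir = a,
                             sza = array(45, c(nd, nt)),
                             qc = array(0L, c(nd, nt)),
                             sensor_id = rep("A", nt))
  flat <- pics_diagnostics(mk(base), 1:4, ep)
  expect_equal(max(abs(flat$anomalies$anomaly_pct)), 0)
  expect_equal(max(flat$discontinuities$discontinuity_pct), 0)

  # +5% of the mean injected at the switch
  stepped <- base
  stepped[, , tm$year >= 1986] <- 0.4 * 1.05
  d <- pics_diagnostics(mk(stepped), 1:4, ep)
  expect_equal(d$discontinuities$discontinuity_pct,
               rep(100 * 0.02 / mean(stepped), 2), tolerance = 1e-6)
  # sanity: the injected |after - before| is 5% of the pre-switch level
  expect_equal(abs(0.42 - 0.4) / 0.4, 0.05)
})

test_that("independent product anomalies show no spurious correlation", {
  g <- grid_spec(3, 3)
  tm <- biweekly_seq(1982, 1997)
  nd <- c(3, 3); nt <- nrow(tm)
  ep <- sensor_epoch_table(1982, c(8, 8), sensor_id = c("A", "B"),
                          group = c("noaa", "metop"))
  set.seed(2)
  hits <- replicate(40, {
    a <- array(0.4 + rnorm(prod(nd) * nt, 0, 0.004), c(nd, nt))
    cube <- new_cube(g, tm, red = a, nir = a, sza = array(45, c(nd, nt)),
                     qc = array(0L, c(nd, nt)), sensor_id = rep("A", nt))
    product <- tibble::tibble(year = 1982:1997, value = rnorm(16))
    d <- pics_diagnostics(cube, 1:5, ep, product = product)
    d$product_correlation$p_value[1] < 0.05
  })
  expect_lt(mean(hits), 0.15)   # ~alpha, independent by construction
})

test_that("trend estimators agree on noiseless lines", {
  y <- 2 * (1:12) + 5
  a <- trend_ols(y, 1:12)
  b <- trend_theil_sen_mk(y, 1:12)
  expect_equal(a$slope_per_decade, 20, tolerance = 1e-10)
  expect_equal(b$slope_per_decade, 20, tolerance = 1e-10)
  expect_lt(b$p_value, 0.01)
  expect_lt(a$p_value, 1e-8)
  # invariance to affine time relabeling
  b2 <- trend_theil_sen_mk(y, 1:12 + 100)
  expect_equal(b2$slope_per_decade, b$slope_per_decade)
  # ties-only series: S = 0, p = 1
  flat <- trend_theil_sen_mk(rep(3, 10), 1:10)
  expect_equal(flat$p_value, 1)
  expect_equal(flat$slope_per_decade, 0)
})

test_that("the modified MK test is calibrated on white and AR(1) noise", {
  # scaled-down check (the acceptance analysis runs 1000 replicates)
  n <- 100
  set.seed(3)
  rej_white <- mean(replicate(300, trend_theil_sen_mk(rnorm(n))$p_value < 0.05))
  expect_lt(abs(rej_white - 0.05), 0.035)
  set.seed(4)
  ps <- replicate(300, {
    y <- ar1_series(n, 0.6)
    mk <- lcspp:::mk_s_var(y)
    c(modified = trend_theil_sen_mk(y)$p_value < 0.05,
      plain = lcspp:::mk_p(mk$s, mk$var) < 0.05)
  })
  expect_gt(mean(ps["plain", ]), 0.15)       # unmodified over-rejects
  expect_lt(abs(mean(ps["modified", ]) - 0.05), 0.045)
})

test_that("growing-season and low-signal masks apply their thresholds strictly", {
  ta <- array(5, c(2, 2, 12))
  expect_false(any(growing_season_mask(ta)))       # 5 C exactly -> out
  ta[1, 1, ] <- 10
  m <- growing_season_mask(ta)
  expect_true(all(m[1, 1, ]))
  expect_false(any(m[2, , ]))

  clim <- matrix(c(0.02, 0.03, 0.5, NA), 2, 2)
  keep <- low_signal_mask(clim)
  expect_equal(as.vector(keep), c(FALSE, TRUE, TRUE, FALSE))  # strict <
})

test_that("area weighting is cos(lat) and preserves constants", {
  lat <- c(60, 30, 0)
  field <- matrix(7, 3, 4)
  expect_equal(area_weighted_mean(field, lat), 7)
  mask <- matrix(TRUE, 3, 4); mask[1, ] <- FALSE
  expect_equal(area_weighted_mean(field, lat, mask), 7)
  # a field varying by row reproduces the cos-weighted mean
  field2 <- matrix(c(1, 2, 3), 3, 4)
  w <- cos(lat * pi / 180)
  expect_equal(area_weighted_mean(field2, lat), sum(w * c(1, 2, 3)) / sum(w))
})

test_that("site comparison filters by QC and runs paired tests by class", {
  set.seed(5)
  n_sites <- 8
  periods <- 1:120
  years <- rep(2001:2005, each = 24)
  gpp <- purrr::map_dfr(seq_len(n_sites), function(s) {
    tibble::tibble(site = s, class = ifelse(s <= 4, "DBF", "GRA"),
                   index = periods, year = years,
                   gpp = 10 + 5 * sin(periods / 4) + rnorm(120),
                   qc = runif(120, 0.5, 1))
  })
  proxies <- purrr::map_dfr(seq_len(n_sites), function(s) {
    g <- dplyr::filter(gpp, site == s)
    dplyr::bind_rows(
      tibble::tibble(site = s, index = periods, proxy = "perfect",
                     value = g$gpp),
      tibble::tibble(site = s, index = periods, proxy = "noisy",
                     value = g$gpp + rnorm(120, 0, 6)))
  })
  res <- site_gpp_comparison(proxies, gpp)
  expect_equal(res$dropped_periods, sum(gpp$qc <= 0.7))
  perfect <- dplyr::filter(res$sites, proxy == "perfect")
  expect_true(all(perfect$r_squared > 1 - 1e-10))
  tests <- res$tests
  expect_equal(sort(unique(tests$class)), c("DBF", "GRA"))
  # the paired test says "perfect beats noisy" in every class
  expect_true(all(tests$p_two_sided < 0.05))
  sign_ok <- ifelse(tests$proxy_a == "perfect",
                    tests$mean_diff > 0, tests$mean_diff < 0)
  expect_true(all(sign_ok))
  one_sided <- ifelse(tests$proxy_a == "perfect",
                      tests$p_one_sided_a_gt_b, 1 - tests$p_one_sided_a_gt_b)
  expect_true(all(one_sided < 0.05))

  # identical proxies -> p = 1 (reported as no difference)
  perfect_rows <- dplyr::filter(proxies, proxy == "perfect")
  res2 <- site_gpp_comparison(
    dplyr::bind_rows(perfect_rows,
                     dplyr::mutate(perfect_rows, proxy = "twin")),
    gpp)
  expect_equal(res2$tests$p_two_sided, rep(1, nrow(res2$tests)))

  # era split honors the minimum-years rule
  res3 <- site_gpp_comparison(proxies, gpp, era_year = 2003, min_years = 3)
  expect_true(all(res3$sites$era %in% c("pre", "post")))
  res4 <- site_gpp_comparison(proxies, gpp, era_year = 2003, min_years = 4)
  expect_equal(nrow(res4$sites), 0)   # nobody has 4 years pre-2003
})

test_that("sites with zero qualifying periods are excluded", {
  gpp <- tibble::tibble(site = rep(1:2, each = 10), class = "DBF",
                        index = rep(1:10, 2), year = 2001,
                        gpp = rnorm(20),
                        qc = rep(c(0.9, 0.1), each = 10))
  proxies <- tibble::tibble(site = rep(1:2, each = 10),
                            index = rep(1:10, 2), proxy = "p",
                            value = rnorm(20))
  res <- site_gpp_comparison(proxies, gpp)
  expect_equal(unique(res$sites$site), 1L)
})
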