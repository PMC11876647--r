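# Shared fixture builders. Everything is generated in code at test time.

# a small biweekly reflectance cube with constant values
tiny_cube <- function(nlat = 3, nlon = 4, years = c(1990, 1990),
                      red = 0.1, nir = 0.4, seed = 1) {
  g <- grid_spec(nlat, nlon)
  tm <- biweekly_seq(years[1], years[2])
  nt <- nrow(tm)
  set.seed(seed)
  mk <- function(v) array(v, c(nlat, nlon, nt))
  new_cube(g, tm, red = mk(red), nir = mk(nir), sza = mk(45),
           qc = array(0L, c(nlat, nlon, nt)),
           sensor_id = rep("N07", nt), class = "refl_cube")
}

# a compact synthetic scene for pipeline tests (kept small for speed)
small_scene <- function(nlat = 12, nlon = 12, years_per_epoch = c(6, 4, 6),
                        n_pics = 10, seed = 5, ...) {
  g <- grid_spec(nlat, nlon)
  truth <- surface_truth_model(g, n_pics = n_pics, seed = seed)
  ep <- sensor_epoch_table(1982, years_per_epoch)
  inj <- artifact_injection(ep, ...)
  simulate_scene(truth, inj, ep, seed = seed + 1L)
}

ar1_series <- function(n, rho, sd = 1) {
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  for (i in 2:n) x[i] <- rho * x[i - 1] + rnorm(1, 0, sd * sqrt(1 - rho^2))
  x
}
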