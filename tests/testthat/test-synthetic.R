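test_that("lattice generation gives a unit-spaced grid with unique ids", {
  cfg <- synth_config(n_side = 3, census_years = c(1900, 1920))
  lat <- generate_county_lattice(cfg)
  expect_equal(nrow(lat), 9)
  expect_setequal(lat$x, 0:2)
  expect_setequal(lat$y, 0:2)
  expect_true(all(lat$land_area > 0))

  big <- generate_county_lattice(synth_config(n_side = 30))
  expect_equal(nrow(big), 900)
  expect_equal(anyDuplicated(big$county_id), 0)

  expect_error(synth_config(n_side = 2), "n_side")
  expect_error(synth_config(census_years = c(1900, 1920, 1930)), "equal spacing")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
})

test_that("monthly climate follows the configured field, seasonality and trend", {
  flat <- list(temp_base = 10, temp_dx = 0, temp_dy = 0,
               temp_bump = c(height = 0, cx = 0, cy = 0, sd = 1),
               temp_ripple = c(amp = 0, fx = 1, fy = 1, phase = 0),
               temp_amp_base = 0, temp_amp_dx = 0, temp_amp_dy = 0,
               temp_amp_ripple = c(amp = 0, fx = 1, fy = 1, phase = 0),
               precip_base = 50, precip_dx = 0, precip_dy = 0,
               precip_bump = c(height = 0, cx = 0, cy = 0, sd = 1),
               precip_ripple = c(amp = 0, fx = 1, fy = 1, phase = 0),
               precip_amp_base = 0, precip_amp_dx = 0, precip_amp_dy = 0,
               precip_amp_ripple = c(amp = 0, fx = 1, fy = 1, phase = 0))
  cfg0 <- synth_config(n_side = 3, census_years = c(1900, 1920),
                       climate = flat, trend_per_year = 0)
  m <- generate_monthly_climate(cfg0, 1901:1902)
  expect_true(all(m$temp == 10))
  expect_true(all(m$precip == 50))

  # amplitude only: yearly temperature SD equals the SD of A*sin(2*pi*m/12)
  amp <- utils::modifyList(flat, list(temp_amp_base = 8))
  cfg1 <- synth_config(n_side = 3, census_years = c(1900, 1920),
                       climate = amp, trend_per_year = 0)
  m1 <- generate_monthly_climate(cfg1, 1901)
  one <- m1[m1$station_id == m1$station_id[1], ]
  expect_equal(nrow(one), 12)
  expect_equal(sd(one$temp), sd(8 * sin(2 * pi * (1:12) / 12)))

  # linear trend: final-year annual mean exceeds the first by 99 * trend
  cfg2 <- synth_config(n_side = 3, census_years = c(1900, 1920),
                       climate = flat, trend_per_year = 0.05)
  m2 <- generate_monthly_climate(cfg2, 1901:2000)
  y <- yearly_climate(m2)
  s1 <- y[y$station_id == y$station_id[1], ]
  expect_equal(s1$annual_temp[s1$year == 2000] - s1$annual_temp[s1$year == 1901],
               99 * 0.05)
  # precipitation never negative under any configuration
  expect_true(all(m2$precip >= 0))
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- synth_config(n_side = 5, seed = 42, census_years = seq(1900, 1940, 20))
  expect_identical(generate_county_lattice(cfg), generate_county_lattice(cfg))
  lat <- generate_county_lattice(cfg)
  expect_identical(generate_covariates(lat, cfg), generate_covariates(lat, cfg))
  expect_identical(synth_dataset(cfg)$counties, synth_dataset(cfg)$counties)
})

test_that("covariates respect their contracts", {
  cfg <- synth_config(n_side = 6, seed = 9, census_years = c(1900, 1920))
  lat <- generate_county_lattice(cfg)
  cov <- generate_covariates(lat, cfg)
  expect_true(all(cov$ag_fraction >= 0 & cov$ag_fraction <= 1))
  expect_true(all(cov$waterway_dist[lat$y == 0] == 0))
  expect_gt(mean(cov$income) / median(cov$income), 1)  # right-skewed
})

test_that("population histories invert the growth model exactly when noiseless", {
  cfg <- synth_config(n_side = 4, seed = 2, noise_sd = 0,
                      census_years = seq(1900, 1960, 20),
                      beta = list(intercept = surface_constant(0)))
  lat <- generate_county_lattice(cfg)
  X <- matrix(rnorm(16), 16, 1, dimnames = list(NULL, "p1"))
  h <- generate_population_history(lat, X, cfg)
  # all-zero coefficients: populations constant across censuses
  expect_equal(h$populations$pop_1900, h$populations$pop_1960)

  # constant beta: recomputed rates equal beta * x exactly
  cfg2 <- synth_config(n_side = 4, seed = 2, noise_sd = 0,
                       census_years = seq(1900, 1960, 20),
                       beta = list(intercept = surface_constant(0.01),
                                   p1 = surface_constant(0.004)))
  h2 <- generate_population_history(lat, X, cfg2)
  lam <- growth_rate(h2$populations$pop_1900, h2$populations$pop_1920, 1900, 1920)
  expect_equal(lam, drop(0.01 + 0.004 * X[, 1]), tolerance = 1e-12)
  expect_equal(lam, unname(h2$truth$true_lambda_mean[, 1]), tolerance = 1e-10)
})

test_that("with noise, recomputed rates sit within 3 noise SDs of truth (RMSE)", {
  cfg <- synth_config(n_side = 30, seed = 8, noise_sd = 0.001,
                      census_years = c(1900, 1920),
                      beta = list(intercept = surface_constant(0.01),
                                  p1 = surface_gradient(0, dx = 0.004,
                                                        center = c(14.5, 14.5))))
  lat <- generate_county_lattice(cfg)
  set.seed(31)
  X <- matrix(rnorm(900), 900, 1, dimnames = list(NULL, "p1"))
  h <- generate_population_history(lat, X, cfg)
  lam <- growth_rate(h$populations$pop_1900, h$populations$pop_1920, 1900, 1920)
  rmse <- sqrt(mean((lam - h$truth$true_lambda_mean[, 1])^2))
  expect_lte(rmse, 3 * cfg$noise_sd)
})

test_that("amplification scenario fixes the climate and drifts exposure warm", {
  cfg <- synth_config(n_side = 6, trend_per_year = 0,
                      census_years = seq(1900, 2000, 20))
  sc <- make_amplification_scenario(cfg, c_rate = 0.003)
  # climate constant in time
  tm <- tapply(sc$normals$annual_temp, sc$normals$census_year, mean)
  expect_true(all(tm == tm[1]))
  # analytic exposure strictly increasing for positive c_rate
  expect_true(all(diff(sc$expected_exposure$exposure) > 0))
  # c_rate = 0: flat trajectory
  sc0 <- make_amplification_scenario(cfg, c_rate = 0)
  expect_true(all(sc0$expected_exposure$exposure ==
                    sc0$expected_exposure$exposure[1]))
  expect_error(make_amplification_scenario(synth_config(n_side = 4)),
               "zero climate trend")
  # two counties, temps 10/20, pops moving 1:1 -> 1:3 give exposure 17.5
  expect_equal(exposure_mean(c(10, 20), c(1, 3)), 17.5)
})

test_that("surface specs evaluate to their closed forms", {
  expect_equal(eval_surface(surface_constant(2), 0:3, 0:3), rep(2, 4))
  g <- surface_gradient(1, dx = 0.5, dy = -1, center = c(2, 2))
  expect_equal(eval_surface(g, c(2, 4), c(2, 2)), c(1, 2))
  b <- surface_bump(3, cx = 1, cy = 1, sd = 2)
  expect_equal(eval_surface(b, 1, 1), 3)
  expect_lt(eval_surface(b, 5, 5), 3 * exp(-1))
})

test_that("a synthetic bundle round-trips through CSV", {
  b <- small_bundle(n_side = 4)
  dir <- tempfile("synth_")
  paths <- write_synth_dataset(b, dir)
  expect_true(all(file.exists(paths)))
  back <- read_counties(paths["counties"])
  expect_equal(back$pop_1900, b$counties$pop_1900)
})
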