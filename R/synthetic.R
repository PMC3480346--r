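## Synthetic county datasets with known ground truth: a planar lattice of
## counties, smooth climate fields with monthly seasonality, census
## populations generated from known coefficient surfaces, and skewed
## socio-economic covariates. Everything is seeded and deterministic.

## Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic generator
#'
#' Defaults are the package's reference study conditions: a 30 x 30 county
#' lattice (900 counties), six censuses 1900-2000 at 20-year spacing, a
#' growth-rate residual SD of 0.01 per year, a climate trend of 0.003 deg C
#' per year, and coefficient surfaces whose across-county spread is of the
#' order of +/-0.05 growth-rate units per predictor SD. See the methods
#' vignette for the rationale behind each value.
#'
#' @param n_side Lattice dimension (>= 3); `n_side^2` counties.
#' @param census_years Strictly increasing, equally spaced census years.
#' @param seed Integer seed governing all randomness.
#' @param noise_sd Non-negative SD of the growth-rate residual (per year).
#' @param beta Named list of `"coef_surface"` objects: the local coefficient
#'   of each (z-scored) predictor, plus an optional `intercept` surface
#'   (baseline growth). Predictors not listed have coefficient zero.
#' @param climate Climate-field specification; see Details.
#' @param trend_per_year Linear temperature drift in deg C per year.
#' @param growth_method Growth-rate form shared with [growth_rate()] /
#'   [project_density()], the single source of truth for the growth model.
#' @param station_offset Offset of station coordinates from county
#'   centroids (default 0: stations coincide with centroids; a nonzero
#'   value exercises nontrivial IDW).
#'
#' @details The monthly temperature at station \eqn{(x, y)} is
#' \deqn{T(x,y,m,yr) = T_{mean}(x,y) + A_T(x,y) \sin(2\pi m/12) +
#'   trend (yr - yr_0),}
#' and precipitation analogously, floored at 0 for physical nonnegativity.
#' The mean fields are `base + dx*x + dy*y` plus two optional smooth
#' components: a Gaussian orographic bump and a low-amplitude sinusoidal
#' mesoscale "ripple" (`amp * sin(fx*x + phase) * cos(fy*y)`); seasonal
#' amplitudes `A` have their own base, linear gradients and ripple. The
#' extras keep the four derived climate fields smooth but non-planar, so
#' that local regression designs with several climate predictors stay full
#' rank (with exact planes they would be locally collinear); setting them to
#' zero recovers the plain gradient-plus-seasonality field.
#'
#' @return A `"synth_config"` list.
#' @export
synth_config <- function(n_side = 30,
                         census_years = seq(1900, 2000, by = 20),
                         seed = 1L,
                         noise_sd = 0.01,
                         beta = NULL,
                         climate = NULL,
                         trend_per_year = 0.003,
                         growth_method = c("log", "geometric"),
                         station_offset = 0) {
  growth_method <- match.arg(growth_method)
  if (!(is.numeric(n_side) && length(n_side) == 1 && n_side >= 3)) {
    stop_domain("configuration error: n_side must be >= 3")
  }
  n_side <- as.integer(n_side)
  if (length(census_years) < 2 || any(diff(census_years) <= 0) ||
      length(unique(diff(census_years))) != 1) {
    stop_domain("configuration error: census_years must be strictly increasing with equal spacing")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop_domain("configuration error: noise_sd must be >= 0")
  }
  ctr <- rep((n_side - 1) / 2, 2)
  if (is.null(beta)) {
    ## gentle effects: per-predictor contributions of order 0.01/yr, so a
    ## century of compounding yields county growth histories (and an
    ## exposure drift) of realistic magnitude
    beta <- list(
      intercept = surface_constant(0.013),
      annual_temp = surface_gradient(0.008, dx = 0.0006, dy = 0, center = ctr),
      income_z = surface_gradient(0.005, dx = 0, dy = 0.0004, center = ctr),
      ag_density = surface_bump(height = 0.01, cx = 0.75 * (n_side - 1),
                                cy = 0.25 * (n_side - 1), sd = 0.27 * n_side)
    )
  }
  if (!all(vapply(beta, inherits, logical(1), "coef_surface"))) {
    stop_domain("configuration error: beta entries must be coef_surface objects")
  }
  default_climate <- list(
    temp_base = 8, temp_dx = 0.4, temp_dy = -0.25,
    temp_bump = c(height = 3, cx = 0.3 * (n_side - 1), cy = 0.7 * (n_side - 1),
                  sd = 0.3 * n_side),
    temp_ripple = c(amp = 1.5, fx = 0.9, fy = 0.7, phase = 0.3),
    temp_amp_base = 8, temp_amp_dx = 0, temp_amp_dy = -0.08,
    temp_amp_ripple = c(amp = 0.8, fx = 0.6, fy = 1.1, phase = 1.2),
    precip_base = 85, precip_dx = -1.2, precip_dy = 0.8,
    precip_bump = c(height = 25, cx = 0.7 * (n_side - 1),
                    cy = 0.2 * (n_side - 1), sd = 0.3 * n_side),
    precip_ripple = c(amp = 8, fx = 1.3, fy = 0.5, phase = 2.1),
    precip_amp_base = 25, precip_amp_dx = 0.4, precip_amp_dy = 0,
    precip_amp_ripple = c(amp = 3, fx = 0.8, fy = 1.4, phase = 0.7)
  )
  if (is.null(climate)) climate <- list()
  climate <- utils::modifyList(default_climate, climate)
  structure(list(n_side = n_side, census_years = census_years,
                 seed = as.integer(seed), noise_sd = noise_sd, beta = beta,
                 climate = climate, trend_per_year = trend_per_year,
                 growth_method = growth_method,
                 station_offset = station_offset),
            class = "synth_config")
}

## Smooth 2-D field: base + gradients + optional bump + optional ripple.
smooth_field <- function(x, y, base, dx, dy, bump = NULL, ripple = NULL) {
  f <- base + dx * x + dy * y
  if (!is.null(bump) && bump[["height"]] != 0) {
    f <- f + bump[["height"]] *
      exp(-((x - bump[["cx"]])^2 + (y - bump[["cy"]])^2) / (2 * bump[["sd"]]^2))
  }
  if (!is.null(ripple) && ripple[["amp"]] != 0) {
    f <- f + ripple[["amp"]] * sin(ripple[["fx"]] * x + ripple[["phase"]]) *
      cos(ripple[["fy"]] * y)
  }
  f
}

climate_mean_fields <- function(config, x, y) {
  cs <- config$climate
  list(
    temp_mean = smooth_field(x, y, cs$temp_base, cs$temp_dx, cs$temp_dy,
                             cs$temp_bump, cs$temp_ripple),
    temp_amp = smooth_field(x, y, cs$temp_amp_base, cs$temp_amp_dx,
                            cs$temp_amp_dy, ripple = cs$temp_amp_ripple),
    precip_mean = smooth_field(x, y, cs$precip_base, cs$precip_dx, cs$precip_dy,
                               cs$precip_bump, cs$precip_ripple),
    precip_amp = smooth_field(x, y, cs$precip_amp_base, cs$precip_amp_dx,
                              cs$precip_amp_dy, ripple = cs$precip_amp_ripple)
  )
}

#' Generate the county lattice
#'
#' `n_side^2` counties on a unit-spaced planar grid with unit land areas and
#' centroid coordinates `{0, ..., n_side - 1}^2`.
#'
#' @param config A [synth_config()].
#' @return Data frame `county_id`, `x`, `y`, `land_area`.
#' @export
generate_county_lattice <- function(config) {
  if (!inherits(config, "synth_config")) stop_domain("configuration error: not a synth_config")
  g <- expand.grid(x = 0:(config$n_side - 1), y = 0:(config$n_side - 1))
  data.frame(county_id = sprintf("c%04d", seq_len(nrow(g))),
             x = g$x, y = g$y, land_area = 1,
             stringsAsFactors = FALSE)
}

#' Generate monthly station climate series
#'
#' Stations sit at the lattice nodes (optionally offset by
#' `station_offset`). Monthly temperature is the smooth mean field plus
#' seasonal amplitude times `sin(2*pi*month/12)` plus the linear trend;
#' precipitation is analogous and floored at 0.
#'
#' @param config A [synth_config()].
#' @param years Year range (non-empty integer vector).
#' @return Monthly data frame as consumed by [yearly_climate()].
#' @export
generate_monthly_climate <- function(config, years) {
  if (!inherits(config, "synth_config")) stop_domain("configuration error: not a synth_config")
  if (length(years) == 0) stop_domain("years must be non-empty")
  lat <- generate_county_lattice(config)
  sx <- lat$x + config$station_offset
  sy <- lat$y + config$station_offset
  fields <- climate_mean_fields(config, sx, sy)
  ns <- nrow(lat)
  ny <- length(years)
  grid <- expand.grid(s = seq_len(ns), month = 1:12, year = years)
  seas <- sin(2 * pi * grid$month / 12)
  drift <- config$trend_per_year * (grid$year - years[1])
  data.frame(
    station_id = lat$county_id[grid$s],
    x = sx[grid$s], y = sy[grid$s],
    year = grid$year, month = grid$month,
    temp = fields$temp_mean[grid$s] + fields$temp_amp[grid$s] * seas + drift,
    precip = pmax(0, fields$precip_mean[grid$s] +
                    fields$precip_amp[grid$s] * seas),
    stringsAsFactors = FALSE
  )
}

#' Generate skewed county covariates
#'
#' Income is log-normal (right-skewed); the agricultural fraction is a
#' noisy east-west gradient clipped to \[0, 1\] and converted to extent via
#' the land area; waterway distance is the distance to the southern lattice
#' edge (y = 0), so counties on that edge have distance 0.
#'
#' @param counties Lattice from [generate_county_lattice()].
#' @param config A [synth_config()].
#' @return Data frame `county_id`, `income`, `ag_fraction`, `ag_extent`,
#'   `waterway_dist`.
#' @export
generate_covariates <- function(counties, config) {
  n <- nrow(counties)
  ctr <- (config$n_side - 1) / 2
  with_seed(config$seed + 1L, {
    income <- stats::rlnorm(n, meanlog = 9.2, sdlog = 0.7)
    frac <- 0.45 + 0.012 * (counties$x - ctr) + stats::rnorm(n, 0, 0.15)
    frac <- pmin(1, pmax(0, frac))
    data.frame(county_id = counties$county_id,
               income = income,
               ag_fraction = frac,
               ag_extent = frac * counties$land_area,
               waterway_dist = counties$y,
               stringsAsFactors = FALSE)
  })
}

#' Generate census population histories from known coefficient surfaces
#'
#' For each 20-year interval, the per-county growth rate is
#' \eqn{\lambda_i = \beta_0(x_i,y_i) + \sum_j \beta_j(x_i,y_i) X_{ij} +
#' \varepsilon_i} with \eqn{\varepsilon \sim N(0, noise\_sd)}, and the
#' population is advanced with [project_density()] — the exact inverse of
#' [growth_rate()] — so that with `noise_sd = 0` the recomputed rates
#' reproduce the recorded truth to machine precision. Populations are kept
#' continuous for that reason.
#'
#' @param counties Lattice from [generate_county_lattice()].
#' @param predictors Per-interval predictor matrices (z-scored, columns
#'   named as in the growth table): a single matrix reused for every
#'   interval, a list with one matrix per interval, or a function
#'   `(interval_index, density_at_start) -> matrix` for dynamic predictors.
#' @param config A [synth_config()].
#' @param initial_population Optional vector of starting populations
#'   (default: seeded log-normal, median 20000).
#' @return List: `populations` (wide data frame `county_id`, `pop_<year>`),
#'   `truth` (list `true_beta` (counties x coefficients, including
#'   `intercept`), `true_lambda_mean` (counties x intervals, noiseless),
#'   `scenario_tag`).
#' @export
generate_population_history <- function(counties, predictors, config,
                                        initial_population = NULL) {
  years <- config$census_years
  K <- length(years) - 1
  n <- nrow(counties)
  get_X <- function(k, dens0) {
    X <- if (is.function(predictors)) predictors(k, dens0)
    else if (is.list(predictors) && !is.data.frame(predictors)) predictors[[k]]
    else predictors
    X <- as.matrix(X)
    if (nrow(X) != n) stop_domain("predictor matrix must have one row per county")
    X
  }
  ## probe for the column set; dynamic builders get a varying dummy density
  X1 <- get_X(1, if (is.function(predictors)) seq_len(n) else NULL)
  pnames <- colnames(X1)
  bnames <- setdiff(names(config$beta), "intercept")
  unknown <- setdiff(bnames, pnames)
  if (length(unknown)) {
    stop_domain("beta surfaces for unavailable predictors: ",
                paste(unknown, collapse = ", "))
  }
  true_beta <- matrix(0, n, length(pnames) + 1,
                      dimnames = list(counties$county_id, c("intercept", pnames)))
  if (!is.null(config$beta$intercept)) {
    true_beta[, "intercept"] <- eval_surface(config$beta$intercept,
                                             counties$x, counties$y)
  }
  for (j in bnames) {
    true_beta[, j] <- eval_surface(config$beta[[j]], counties$x, counties$y)
  }

  pop <- matrix(NA_real_, n, K + 1,
                dimnames = list(NULL, paste0("pop_", years)))
  lambda_mean <- matrix(NA_real_, n, K,
                        dimnames = list(counties$county_id,
                                        paste(years[-(K + 1)], years[-1], sep = "_")))
  with_seed(config$seed + 2L, {
    pop[, 1] <- if (is.null(initial_population)) {
      stats::rlnorm(n, meanlog = log(20000), sdlog = 1)
    } else initial_population
    for (k in seq_len(K)) {
      dens0 <- population_density(pop[, k], counties$land_area)
      X <- get_X(k, dens0)
      lam0 <- true_beta[, "intercept"] +
        rowSums(X[, pnames, drop = FALSE] * true_beta[, pnames, drop = FALSE])
      lambda_mean[, k] <- lam0
      eps <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else 0
      dens1 <- project_density(dens0, lam0 + eps, years[k], years[k + 1],
                               method = config$growth_method)
      if (any(!is.finite(dens1)) || any(dens1 <= 0)) {
        stop_domain("generation error: population underflow; shrink noise or horizon")
      }
      pop[, k + 1] <- dens1 * counties$land_area
    }
  })
  list(populations = data.frame(county_id = counties$county_id, pop,
                                stringsAsFactors = FALSE),
       truth = list(true_beta = true_beta, true_lambda_mean = lambda_mean,
                    scenario_tag = "coefficient-surface growth"))
}

#' Full synthetic dataset bundle
#'
#' Chains the lattice, covariate, climate and population generators into
#' the complete input set for the pipeline, with ground truth attached. The
#' growth model's predictors are the z-scored (within interval) versions of
#' the same transformed variables the growth table exposes, so estimated
#' coefficient surfaces are directly comparable to `truth$true_beta`.
#'
#' @param config A [synth_config()].
#' @return List with `config`, `counties` (wide table with populations and
#'   covariates), `covariates`, `monthly`, `station_normals`,
#'   `county_normals`, `populations_long`, and `truth`.
#' @export
synth_dataset <- function(config = synth_config()) {
  lat <- generate_county_lattice(config)
  cov <- generate_covariates(lat, config)
  years <- config$census_years
  hz <- assign_horizon(years, years)
  monthly <- generate_monthly_climate(config, min(hz$start_year):max(hz$end_year))
  st_norm <- climate_normals(monthly, years)
  co_norm <- county_climate(st_norm, lat)

  ag_dens <- agricultural_density(cov$ag_extent, lat$land_area)
  income_z <- zscore(cov$income)
  K <- length(years) - 1
  build_X <- function(k, dens0) {
    cli <- co_norm[co_norm$census_year == years[k], , drop = FALSE]
    cli <- cli[match(lat$county_id, cli$county_id), , drop = FALSE]
    X <- cbind(annual_temp = zscore(cli$annual_temp),
               temp_seasonality = zscore(cli$temp_seasonality),
               annual_precip = zscore(cli$annual_precip),
               precip_seasonality = zscore(cli$precip_seasonality),
               income_z = income_z,
               ag_density = zscore(ag_dens),
               waterway_sqrt = zscore(waterway_sqrt(cov$waterway_dist)))
    if (!is.null(dens0)) {
      X <- cbind(X, log_density = zscore(log_density(dens0)))
    }
    X
  }
  hist <- generate_population_history(lat, build_X, config)

  counties <- cbind(lat, hist$populations[-1],
                    cov[c("income", "ag_extent", "waterway_dist")])
  pl <- do.call(rbind, lapply(years, function(yr) {
    data.frame(county_id = counties$county_id, census_year = yr,
               population = counties[[paste0("pop_", yr)]],
               stringsAsFactors = FALSE)
  }))
  list(config = config, counties = counties, covariates = cov,
       monthly = monthly, station_normals = st_norm, county_normals = co_norm,
       populations_long = pl, truth = hist$truth)
}

#' Engineered demographic-amplification scenario
#'
#' A bundle in which the climate is constant in time (zero trend required)
#' while the growth rate increases strictly with county temperature
#' (\eqn{\lambda_i = c T_i}), so the area-averaged climate never changes
#' but the population-weighted exposure drifts warm. The analytically
#' expected exposure trajectory
#' \eqn{E(t) = \sum_i T_i p_i(t) / \sum_i p_i(t)} is computed from the
#' generating rule and bundled for comparison against the niche module.
#'
#' @param config A [synth_config()] with `trend_per_year = 0`.
#' @param c_rate Growth-rate increment per deg C (default 0.002; positive
#'   makes exposure strictly increasing).
#' @param initial_population Starting populations (default: equal, 10000).
#' @return List: `counties`, `temps`, `populations_long`, `normals`
#'   (constant `annual_temp` per census), `expected_exposure` (data frame
#'   `census_year`, `exposure`), `c_rate`, `scenario_tag`.
#' @export
make_amplification_scenario <- function(config = synth_config(n_side = 10,
                                                              trend_per_year = 0),
                                        c_rate = 0.002,
                                        initial_population = NULL) {
  if (config$trend_per_year != 0) {
    stop_domain("amplification scenario requires zero climate trend")
  }
  lat <- generate_county_lattice(config)
  n <- nrow(lat)
  temps <- climate_mean_fields(config, lat$x, lat$y)$temp_mean
  years <- config$census_years
  p0 <- if (is.null(initial_population)) rep(10000, n) else initial_population
  lam <- c_rate * temps
  pops <- vapply(years, function(t) {
    dens <- population_density(p0, lat$land_area)
    if (t == years[1]) p0
    else project_density(dens, lam, years[1], t,
                         method = config$growth_method) * lat$land_area
  }, numeric(n))
  colnames(pops) <- paste0("pop_", years)
  expected <- vapply(seq_along(years), function(k) {
    sum(temps * pops[, k]) / sum(pops[, k])
  }, numeric(1))
  pl <- do.call(rbind, lapply(seq_along(years), function(k) {
    data.frame(county_id = lat$county_id, census_year = years[k],
               population = pops[, k], stringsAsFactors = FALSE)
  }))
  normals <- do.call(rbind, lapply(years, function(yr) {
    data.frame(county_id = lat$county_id, census_year = yr,
               annual_temp = temps, stringsAsFactors = FALSE)
  }))
  list(counties = cbind(lat, pops), temps = temps, populations_long = pl,
       normals = normals,
       expected_exposure = data.frame(census_year = years, exposure = expected),
       c_rate = c_rate, scenario_tag = "amplification")
}

#' Write a synthetic bundle to CSV (plus JSON config)
#'
#' @param bundle Output of [synth_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_synth_dataset <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counties = file.path(dir, "counties.csv"),
    covariates = file.path(dir, "covariates.csv"),
    monthly = file.path(dir, "monthly_climate.csv"),
    county_normals = file.path(dir, "county_normals.csv"),
    truth_beta = file.path(dir, "truth_beta.csv"),
    truth_lambda = file.path(dir, "truth_lambda.csv"),
    config = file.path(dir, "config.json")
  )
  utils::write.csv(bundle$counties, paths["counties"], row.names = FALSE)
  utils::write.csv(bundle$covariates, paths["covariates"], row.names = FALSE)
  utils::write.csv(bundle$monthly, paths["monthly"], row.names = FALSE)
  utils::write.csv(bundle$county_normals, paths["county_normals"], row.names = FALSE)
  utils::write.csv(data.frame(county_id = rownames(bundle$truth$true_beta),
                              bundle$truth$true_beta, check.names = FALSE),
                   paths["truth_beta"], row.names = FALSE)
  utils::write.csv(data.frame(county_id = rownames(bundle$truth$true_lambda_mean),
                              bundle$truth$true_lambda_mean, check.names = FALSE),
                   paths["truth_lambda"], row.names = FALSE)
  cfg <- bundle$config
  cfg$beta <- lapply(cfg$beta, unclass)
  jsonlite::write_json(unclass(cfg), paths["config"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
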