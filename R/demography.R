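## Demographic quantities: densities, interval growth rates, and the
## transformed non-climate predictors used alongside climate normals.

#' Population density
#'
#' Density of a county: total population divided by land area.
#'
#' @param population Non-negative population count (vectorised).
#' @param land_area Positive land area, same spatial units throughout the
#'   analysis (km^2 for geographic data, lattice units^2 for synthetic data).
#' @return Population per unit area.
#' @examples
#' population_density(281, 2) # 140.5
#' @export
population_density <- function(population, land_area) {
  check_number(population, "population", nonneg = TRUE)
  if (!is.numeric(land_area) || anyNA(land_area) || any(land_area <= 0)) {
    stop_domain("land_area must be > 0")
  }
  population / land_area
}

#' Annual growth rate of population density over a census interval
#'
#' The demographic growth rate \eqn{\lambda} over an interval
#' \eqn{[t_0, t_1]} is, in the default continuous form,
#' \deqn{\lambda = \log(hd_1 / hd_0) / (t_1 - t_0),}
#' the instantaneous annual rate implied by the density change. The
#' alternative geometric form \eqn{(hd_1/hd_0)^{1/(t_1-t_0)} - 1} is the
#' discrete annual rate. Both depend only on the density ratio, so the rate
#' is mathematically independent of the density level itself and free to
#' correlate (or not) with it empirically.
#'
#' @param hd0,hd1 Positive densities at the start and end of the interval.
#' @param t0,t1 Interval years, `t1 > t0`.
#' @param method `"log"` (default, continuous rate) or `"geometric"`.
#' @return Growth rate per year (vectorised over densities).
#' @seealso [project_density()] for the exact inverse.
#' @examples
#' growth_rate(100, 200, 1900, 1920) # log(2)/20
#' @export
growth_rate <- function(hd0, hd1, t0, t1, method = c("log", "geometric")) {
  method <- match.arg(method)
  check_number(hd0, "hd0", positive = TRUE)
  check_number(hd1, "hd1", positive = TRUE)
  if (any(t1 <= t0)) stop_domain("t1 must be greater than t0")
  dt <- t1 - t0
  if (method == "log") log(hd1 / hd0) / dt else (hd1 / hd0)^(1 / dt) - 1
}

#' Advance a density by a growth rate (inverse of [growth_rate()])
#'
#' Single source of truth for the growth model: projecting `hd0` forward by
#' `lambda` and recomputing the rate with the same `method` round-trips
#' exactly.
#'
#' @inheritParams growth_rate
#' @param lambda Growth rate per year.
#' @return Density at `t1`.
#' @export
project_density <- function(hd0, lambda, t0, t1, method = c("log", "geometric")) {
  method <- match.arg(method)
  check_number(hd0, "hd0", positive = TRUE)
  if (any(t1 <= t0)) stop_domain("t1 must be greater than t0")
  dt <- t1 - t0
  if (method == "log") hd0 * exp(lambda * dt) else hd0 * (1 + lambda)^dt
}

#' Base-10 log of density
#'
#' Density distributions across counties are strongly right-skewed; the
#' log10 transform normalises them before use as a predictor.
#'
#' @param hd Positive density.
#' @export
log_density <- function(hd) {
  if (!is.numeric(hd) || anyNA(hd) || any(hd <= 0)) {
    stop_domain("density must be > 0 for log transform")
  }
  log10(hd)
}

#' Within-group z-scores
#'
#' Centres and scales by the sample standard deviation (denominator
#' \eqn{n-1}); used to standardise income within each census and, in the
#' regression module, every predictor and the response.
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @return Vector with mean 0 and sample SD 1.
#' @export
zscore <- function(values) {
  check_number(values, "values")
  if (length(values) < 2) stop_domain("zscore needs at least 2 values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop_domain("zscore undefined: zero standard deviation")
  (values - mean(values)) / s
}

#' Weighted interpolation of income z-scores between censuses
#'
#' Income for a census with no usable economic query is interpolated from
#' the two flanking censuses as `w_a * z_a + w_b * z_b`; the historical
#' weighting for 1960 is 0.333 on the 1940 estimate and 0.667 on the 1970
#' estimate.
#'
#' @param z_a,z_b Income z-scores at the flanking censuses.
#' @param w_a,w_b Weights, summing to 1 (within 1e-9).
#' @export
interpolate_income <- function(z_a, z_b, w_a = 0.333, w_b = 0.667) {
  if (abs(w_a + w_b - 1) > 1e-9) {
    stop_domain("interpolation weights must sum to 1")
  }
  w_a * z_a + w_b * z_b
}

#' Mean income from categorical (binned) census income counts
#'
#' For censuses reporting persons per income range, mean income is the
#' count-weighted average of the category midpoints.
#'
#' @param counts Non-negative integer counts per category.
#' @param bounds Two-column matrix (or 2-vector for one category) of
#'   category `(low, high)` bounds; midpoint = (low + high)/2.
#' @export
categorical_income_mean <- function(counts, bounds) {
  if (is.vector(bounds)) bounds <- matrix(bounds, ncol = 2, byrow = TRUE)
  check_number(counts, "counts", nonneg = TRUE)
  if (nrow(bounds) != length(counts)) {
    stop_domain("counts and bounds must align")
  }
  if (any(bounds[, 1] >= bounds[, 2])) stop_domain("category bounds must satisfy low < high")
  if (sum(counts) <= 0) stop_domain("at least one category count must be positive")
  mid <- (bounds[, 1] + bounds[, 2]) / 2
  sum(counts * mid) / sum(counts)
}

#' Arc-sine square-root transformed agricultural density
#'
#' Crop-plus-pasture extent as a fraction of county land area, variance
#' stabilised by \eqn{\arcsin\sqrt{f}}; fractions above 1 (possible with
#' inconsistent source areas) are clipped to 1.
#'
#' @param ag_extent Non-negative agricultural extent, same units as
#'   `land_area`.
#' @param land_area Positive land area.
#' @return Value in \[0, pi/2\] (radians).
#' @export
agricultural_density <- function(ag_extent, land_area) {
  if (!is.numeric(ag_extent) || anyNA(ag_extent) || any(ag_extent < 0)) {
    stop_domain("ag_extent must be >= 0")
  }
  if (any(land_area <= 0)) stop_domain("land_area must be > 0")
  asin(sqrt(pmin(1, ag_extent / land_area)))
}

#' Square-root transformed waterway distance
#'
#' @param d Non-negative distance from the county centroid to the nearest
#'   major waterway.
#' @export
waterway_sqrt <- function(d) {
  if (!is.numeric(d) || anyNA(d) || any(d < 0)) stop_domain("distance must be >= 0")
  sqrt(d)
}

#' Keep only counties with a population at every census year
#'
#' Mirrors the restriction of the analysis to counties with stable
#' boundaries and complete census coverage; input order is preserved.
#'
#' @param counties Wide county data frame with columns `pop_<year>`.
#' @param census_years Census years that must all be present and non-missing.
#' @return The complete subset, same column structure.
#' @export
filter_complete_counties <- function(counties, census_years) {
  cols <- paste0("pop_", census_years)
  missing_cols <- setdiff(cols, names(counties))
  keep <- if (length(missing_cols)) {
    rep(FALSE, nrow(counties))
  } else {
    stats::complete.cases(counties[cols])
  }
  if (!any(keep)) stop_domain("no county has complete census coverage")
  counties[keep, , drop = FALSE]
}

#' Assemble the growth table: per-county, per-interval rates and predictors
#'
#' For each consecutive pair of census years, computes the growth rate of
#' population density and attaches the eight predictors evaluated at the
#' interval start: the four climate normals of the horizon assigned to the
#' start year, log10 density, the within-census income z-score, arc-sine
#' square-root agricultural density, and square-root waterway distance.
#'
#' Income handling: a column `income_<year>` is used if present, else a
#' static `income` column. Counties with missing income at an interval start
#' are interpolated from the flanking censuses when both are present
#' (weights proportional to proximity in time) and otherwise dropped from
#' that interval with a warning. Agricultural extent likewise accepts
#' `ag_<year>` columns or a static `ag_extent`.
#'
#' @param counties Wide county table: `county_id`, `x`, `y`, `land_area`,
#'   `pop_<year>` columns, income and agriculture columns as above, and
#'   `waterway_dist`.
#' @param normals County climate normals as returned by [county_climate()]:
#'   `county_id`, `census_year`, the four climate variables.
#' @param census_years Ordered census years (default 1900-2000 by 20).
#' @param method Growth-rate form, see [growth_rate()].
#' @return Data frame with columns `county_id`, `t0`, `t1`, `lambda`,
#'   `annual_temp`, `temp_seasonality`, `annual_precip`,
#'   `precip_seasonality`, `log_density`, `income_z`, `ag_density`,
#'   `waterway_sqrt`.
#' @export
build_growth_table <- function(counties, normals,
                               census_years = seq(1900, 2000, by = 20),
                               method = c("log", "geometric")) {
  method <- match.arg(method)
  counties <- filter_complete_counties(counties, census_years)
  n <- nrow(counties)

  income_at <- function(year) {
    col <- paste0("income_", year)
    if (col %in% names(counties)) counties[[col]] else counties[["income"]]
  }
  ## z-score income within census, interpolating from flanking censuses
  ## where the focal census is missing for some counties.
  income_z_at <- function(year) {
    inc <- income_at(year)
    if (is.null(inc)) stop_domain("no income column for census ", year)
    z <- rep(NA_real_, n)
    ok <- !is.na(inc)
    if (sum(ok) >= 2) z[ok] <- zscore(inc[ok])
    if (any(!ok)) {
      others <- census_years[census_years != year]
      prev <- rev(others[others < year])
      nxt <- others[others > year]
      if (length(prev) && length(nxt)) {
        ya <- prev[1]; yb <- nxt[1]
        za <- income_z_at_simple(ya); zb <- income_z_at_simple(yb)
        wb <- (year - ya) / (yb - ya)
        fill <- !ok & !is.na(za) & !is.na(zb)
        z[fill] <- interpolate_income(za[fill], zb[fill], 1 - wb, wb)
      }
    }
    z
  }
  income_z_at_simple <- function(year) {
    inc <- income_at(year)
    if (is.null(inc)) return(rep(NA_real_, n))
    z <- rep(NA_real_, n)
    ok <- !is.na(inc)
    if (sum(ok) >= 2) z[ok] <- zscore(inc[ok])
    z
  }
  ag_at <- function(year) {
    col <- paste0("ag_", year)
    if (col %in% names(counties)) counties[[col]] else counties[["ag_extent"]]
  }

  out <- vector("list", length(census_years) - 1)
  for (k in seq_len(length(census_years) - 1)) {
    t0 <- census_years[k]; t1 <- census_years[k + 1]
    hd0 <- population_density(counties[[paste0("pop_", t0)]], counties$land_area)
    hd1 <- population_density(counties[[paste0("pop_", t1)]], counties$land_area)
    lam <- growth_rate(hd0, hd1, t0, t1, method = method)

    cli <- normals[normals$census_year == t0, , drop = FALSE]
    idx <- match(counties$county_id, cli$county_id)
    if (anyNA(idx)) stop_domain("climate normals missing for census ", t0)

    tab <- data.frame(
      county_id = counties$county_id,
      t0 = t0, t1 = t1, lambda = lam,
      annual_temp = cli$annual_temp[idx],
      temp_seasonality = cli$temp_seasonality[idx],
      annual_precip = cli$annual_precip[idx],
      precip_seasonality = cli$precip_seasonality[idx],
      log_density = log_density(hd0),
      income_z = income_z_at(t0),
      ag_density = agricultural_density(ag_at(t0), counties$land_area),
      waterway_sqrt = waterway_sqrt(counties$waterway_dist),
      stringsAsFactors = FALSE
    )
    drop <- is.na(tab$income_z)
    if (any(drop)) {
      warning(sprintf("interval %d-%d: dropping %d counties with unrecoverable income",
                      t0, t1, sum(drop)), call. = FALSE)
      tab <- tab[!drop, , drop = FALSE]
    }
    out[[k]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Predictor names used throughout the analysis
#'
#' @return Named list with elements `climate` and `nonclimate`.
#' @export
predictor_groups <- function() {
  list(
    climate = c("annual_temp", "temp_seasonality", "annual_precip",
                "precip_seasonality"),
    nonclimate = c("log_density", "income_z", "ag_density", "waterway_sqrt")
  )
}

#' Read a county table from CSV
#'
#' Expects the documented wide header: `county_id, x, y, land_area,
#' pop_<year>..., income[_<year>]..., ag[_<year>]..., waterway_dist`.
#'
#' @param path CSV path.
#' @export
read_counties <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
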