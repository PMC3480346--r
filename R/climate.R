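## Climate module: four variables from monthly station series, 20-year
## horizon averages, and inverse-distance interpolation to county centroids.

#' Yearly climate summaries from monthly series
#'
#' Collapses a monthly station table to one row per station-year with the
#' four climate variables: mean of the 12 monthly temperatures, their sample
#' standard deviation (temperature seasonality), the sum of the 12 monthly
#' precipitation totals, and their sample standard deviation (precipitation
#' seasonality).
#'
#' @param monthly Data frame with columns `station_id`, `x`, `y`, `year`,
#'   `month` (1-12), `temp` (deg C monthly mean), `precip` (mm monthly
#'   total). Every station-year must have exactly 12 months.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return Data frame: `station_id`, `x`, `y`, `year`, `annual_temp`,
#'   `temp_seasonality`, `annual_precip`, `precip_seasonality`.
#' @export
yearly_climate <- function(monthly, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  need <- c("station_id", "x", "y", "year", "month", "temp", "precip")
  if (!all(need %in% names(monthly))) {
    stop_domain("monthly series needs columns: ", paste(need, collapse = ", "))
  }
  if (any(monthly$precip < 0)) stop_domain("precip must be >= 0")
  key <- paste(monthly$station_id, monthly$year, sep = "\r")
  cnt <- table(key)
  bad <- names(cnt)[cnt != 12L]
  if (length(bad)) {
    stop_domain("incomplete station-year (need 12 months): ",
                paste(gsub("\r", " year ", utils::head(bad, 3)), collapse = "; "))
  }
  if (anyDuplicated(paste(key, monthly$month, sep = "\r"))) {
    stop_domain("duplicate station-year-month rows")
  }
  g <- factor(key)
  denom <- if (sd_type == "sample") 11 else 12
  tmean <- rowsum(monthly$temp, g) / 12
  pmean <- rowsum(monthly$precip, g) / 12
  gi <- as.integer(g)
  ## two-pass SD: centring before squaring avoids cancellation error
  tsq <- rowsum((monthly$temp - tmean[gi])^2, g)
  psq <- rowsum((monthly$precip - pmean[gi])^2, g)
  psum <- pmean * 12
  first <- !duplicated(g)
  meta <- monthly[first, c("station_id", "x", "y", "year")]
  meta <- meta[order(g[first]), , drop = FALSE]
  data.frame(
    station_id = meta$station_id, x = meta$x, y = meta$y, year = meta$year,
    annual_temp = drop(tmean),
    temp_seasonality = sqrt(drop(tsq) / denom),
    annual_precip = drop(psum),
    precip_seasonality = sqrt(drop(psq) / denom),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Assign the 20-year climate horizon of a census year
#'
#' Each census year is paired with the preceding 20 climate years,
#' `(year - 19, year)`; 1900 predates the instrumental record used, so it
#' shares the 1901-1920 horizon with the 1920 census.
#'
#' @param census_year One or more census years from `census_years`.
#' @param census_years The configured census set.
#' @return Data frame with `census_year`, `start_year`, `end_year`.
#' @export
assign_horizon <- function(census_year, census_years = seq(1900, 2000, by = 20)) {
  if (!all(census_year %in% census_years)) {
    stop_domain("census year not in configured set: ",
                paste(setdiff(census_year, census_years), collapse = ", "))
  }
  start <- ifelse(census_year == 1900, 1901, census_year - 19)
  end <- ifelse(census_year == 1900, 1920, census_year)
  data.frame(census_year = census_year, start_year = start, end_year = end)
}

#' Average yearly climate over a horizon
#'
#' Arithmetic mean, per variable, of the yearly summaries across the 20
#' years (in general `end - start + 1` years) of a temporal horizon; every
#' year must be present.
#'
#' @param yearly Output of [yearly_climate()] for one or more stations.
#' @param start_year,end_year Inclusive horizon bounds.
#' @return One row per station: `station_id`, `x`, `y`, `start_year`,
#'   `end_year`, and the four averaged variables.
#' @export
horizon_average <- function(yearly, start_year, end_year) {
  span <- start_year:end_year
  sub <- yearly[yearly$year %in% span, , drop = FALSE]
  cnt <- table(sub$station_id)
  if (length(cnt) == 0L || any(cnt != length(span))) {
    stop_domain("incomplete horizon ", start_year, "-", end_year,
                ": every station needs all ", length(span), " years")
  }
  g <- factor(sub$station_id)
  vars <- c("annual_temp", "temp_seasonality", "annual_precip", "precip_seasonality")
  m <- rowsum(as.matrix(sub[vars]), g) / length(span)
  first <- !duplicated(g)
  meta <- sub[first, c("station_id", "x", "y")]
  meta <- meta[order(g[first]), , drop = FALSE]
  out <- data.frame(meta, start_year = start_year, end_year = end_year,
                    m, row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Station climate normals for each census year
#'
#' Runs [yearly_climate()] then [horizon_average()] for the horizon assigned
#' to every census year.
#'
#' @inheritParams yearly_climate
#' @param census_years Census years whose horizons are wanted.
#' @return Data frame keyed by `station_id` and `census_year`.
#' @export
climate_normals <- function(monthly, census_years = seq(1900, 2000, by = 20),
                            sd_type = c("sample", "population")) {
  yearly <- yearly_climate(monthly, sd_type = match.arg(sd_type))
  hz <- assign_horizon(census_years, census_years)
  out <- vector("list", nrow(hz))
  for (i in seq_len(nrow(hz))) {
    h <- horizon_average(yearly, hz$start_year[i], hz$end_year[i])
    h$census_year <- hz$census_year[i]
    out[[i]] <- h
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Inverse-distance-weighted interpolation
#'
#' Interpolates station values to target points with weights
#' \eqn{w_i = d_i^{-power}}. A target coinciding with a station (distance 0)
#' receives that station's value exactly; results are always bounded by the
#' station extremes.
#'
#' @param sx,sy Station coordinates.
#' @param values Station values: vector, or matrix with one column per
#'   variable (rows = stations).
#' @param tx,ty Target coordinates.
#' @param power Positive distance-decay exponent (default 2).
#' @return Matrix of interpolated values, `length(tx)` rows.
#' @export
idw_interpolate <- function(sx, sy, values, tx, ty, power = 2) {
  if (length(sx) == 0L) stop_domain("at least one station required")
  check_number(power, "power", positive = TRUE)
  values <- as.matrix(values)
  if (nrow(values) != length(sx)) stop_domain("values must have one row per station")
  out <- matrix(NA_real_, length(tx), ncol(values),
                dimnames = list(NULL, colnames(values)))
  for (j in seq_along(tx)) {
    d <- sqrt((sx - tx[j])^2 + (sy - ty[j])^2)
    hit <- which(d == 0)
    if (length(hit)) {
      out[j, ] <- values[hit[1L], ]
    } else {
      w <- d^(-power)
      out[j, ] <- colSums(values * w) / sum(w)
    }
  }
  out
}

#' Climate normals at county centroids
#'
#' Interpolates station normals ([climate_normals()]) to county centroids by
#' IDW, per census year and variable. Distances are planar Euclidean in the
#' input coordinates (degrees for geographic data, lattice units for
#' synthetic data).
#'
#' @param station_normals Output of [climate_normals()].
#' @param counties County table with `county_id`, `x`, `y`.
#' @param power IDW exponent.
#' @return Data frame: `county_id`, `census_year`, four climate variables.
#' @export
county_climate <- function(station_normals, counties, power = 2) {
  vars <- c("annual_temp", "temp_seasonality", "annual_precip", "precip_seasonality")
  out <- vector("list", 0L)
  for (yr in unique(station_normals$census_year)) {
    st <- station_normals[station_normals$census_year == yr, , drop = FALSE]
    vals <- idw_interpolate(st$x, st$y, as.matrix(st[vars]),
                            counties$x, counties$y, power = power)
    out[[length(out) + 1L]] <- data.frame(
      county_id = counties$county_id, census_year = yr, vals,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
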