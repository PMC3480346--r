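## Niche module: population-weighted climate exposure vs area-averaged
## climate change, and the smoothed abundance surface in climate space.

#' Population-weighted mean climate ("climate exposure")
#'
#' The climate experienced by the average person:
#' \eqn{\sum_i w_i c_i / \sum_i w_i} with county populations as weights.
#' Invariant to uniform rescaling of the weights and bounded by the county
#' extremes.
#'
#' @param values Per-county climate values.
#' @param weights Per-county populations (non-negative, positive total).
#' @export
exposure_mean <- function(values, weights) {
  if (length(values) != length(weights)) stop_domain("values and weights must align")
  check_number(weights, "weights", nonneg = TRUE)
  tot <- sum(weights)
  if (tot <= 0) stop_domain("total weight must be > 0")
  ## uniform weights reduce to the plain mean; computing it as such keeps
  ## the exposure/area identity exact in floating point
  if (all(weights == weights[1])) return(mean(values))
  sum(values * weights) / tot
}

#' Unweighted county mean climate ("climate change" baseline)
#'
#' @param values Per-county climate values (non-empty).
#' @export
area_mean <- function(values) {
  if (length(values) == 0L) stop_domain("area_mean of empty vector")
  mean(values)
}

#' Exposure and area-mean trajectories across censuses
#'
#' For each census year and climate variable, computes the
#' population-weighted exposure mean and the unweighted area mean, plus the
#' change in each between two endpoint years. Because a shared climate
#' horizon can serve two censuses (1900 and 1920 share 1901-1920), the area
#' mean is reported as `NA` for years in `omit_area_years`: its value would
#' duplicate the later census while the exposure mean still differs through
#' the populations.
#'
#' @param normals County normals (`county_id`, `census_year`, variables).
#' @param populations Long table `county_id`, `census_year`, `population`.
#' @param census_years Census years to include.
#' @param variables Climate variable names (default annual temperature and
#'   temperature seasonality).
#' @param endpoints Two years between which deltas are computed
#'   (default 1920 and 2000, clipped to available years).
#' @param omit_area_years Years whose area mean is flagged `NA` (default
#'   1900 when present).
#' @return Object of class `"exposure_trajectory"`: list with `trajectory`
#'   (year x variable table of exposure and area means) and `deltas` (per
#'   variable: `delta_exposure`, `delta_area`, `amplification`).
#' @export
exposure_trajectory <- function(normals, populations, census_years,
                                variables = c("annual_temp", "temp_seasonality"),
                                endpoints = c(1920, 2000),
                                omit_area_years = intersect(1900, census_years)) {
  rows <- vector("list", 0L)
  for (yr in census_years) {
    cli <- normals[normals$census_year == yr, , drop = FALSE]
    pop <- populations[populations$census_year == yr, , drop = FALSE]
    if (nrow(cli) == 0L || nrow(pop) == 0L) {
      stop_domain("missing normals or populations for census ", yr)
    }
    idx <- match(cli$county_id, pop$county_id)
    if (anyNA(idx)) stop_domain("populations missing for some counties in ", yr)
    w <- pop$population[idx]
    for (v in variables) {
      rows[[length(rows) + 1L]] <- data.frame(
        census_year = yr, variable = v,
        exposure_mean = exposure_mean(cli[[v]], w),
        area_mean = if (yr %in% omit_area_years) NA_real_ else area_mean(cli[[v]]),
        stringsAsFactors = FALSE
      )
    }
  }
  traj <- do.call(rbind, rows)

  endpoints <- sort(endpoints)
  if (!all(endpoints %in% census_years)) {
    endpoints <- range(setdiff(census_years, omit_area_years))
  }
  deltas <- do.call(rbind, lapply(variables, function(v) {
    tv <- traj[traj$variable == v, , drop = FALSE]
    e <- tv$exposure_mean[match(endpoints, tv$census_year)]
    a <- tv$area_mean[match(endpoints, tv$census_year)]
    de <- e[2] - e[1]
    da <- a[2] - a[1]
    ## area changes at rounding-noise level (relative to the variable's
    ## magnitude) count as zero rather than producing absurd ratios
    amp <- amplification_ratio(de, da,
                               tol = 1e-9 * max(1, abs(a), na.rm = TRUE))
    data.frame(variable = v, from = endpoints[1], to = endpoints[2],
               delta_exposure = de, delta_area = da,
               amplification = as.numeric(amp),
               amplification_defined = !isTRUE(attr(amp, "undefined")),
               stringsAsFactors = FALSE)
  }))
  structure(list(trajectory = traj, deltas = deltas,
                 endpoints = endpoints),
            class = "exposure_trajectory")
}

#' @export
print.exposure_trajectory <- function(x, digits = 4, ...) {
  cat("Climate exposure vs area-averaged climate trajectory\n")
  cat(sprintf("Endpoint deltas (%d -> %d):\n", x$endpoints[1], x$endpoints[2]))
  print(format(x$deltas, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Ratio of exposure change to area-averaged climate change
#'
#' Values above 1 indicate demographic amplification: the population-weighted
#' climate moved further than the climate itself. Undefined when the area
#' change is zero; the result is then `NA` carrying attribute
#' `undefined = TRUE` rather than an error.
#'
#' @param delta_exposure Change in population-weighted mean.
#' @param delta_area Change in unweighted county mean.
#' @param tol Magnitude below which the area change counts as zero
#'   (default 0: only an exact zero is undefined).
#' @export
amplification_ratio <- function(delta_exposure, delta_area, tol = 0) {
  if (is.na(delta_area) || abs(delta_area) <= tol) {
    return(structure(NA_real_, undefined = TRUE))
  }
  delta_exposure / delta_area
}

#' Additive decomposition of an exposure change
#'
#' Splits the change in exposure between two censuses into a climate
#' component (climate updated, populations frozen at the start) and a
#' demographic component (populations updated, climate frozen). The two
#' components sum to the total exactly when the cross term vanishes, e.g.
#' under a spatially uniform climate shift.
#'
#' @param values_a,values_b Per-county climate at start and end.
#' @param weights_a,weights_b Per-county populations at start and end.
#' @export
exposure_decomposition <- function(values_a, values_b, weights_a, weights_b) {
  e_aa <- exposure_mean(values_a, weights_a)
  e_ba <- exposure_mean(values_b, weights_a)
  e_ab <- exposure_mean(values_a, weights_b)
  e_bb <- exposure_mean(values_b, weights_b)
  list(total = e_bb - e_aa,
       climate_component = e_ba - e_aa,
       demographic_component = e_ab - e_aa,
       cross_term = (e_bb - e_aa) - (e_ba - e_aa) - (e_ab - e_aa))
}

#' Define binning axes over climate space
#'
#' @param values Observed values of one climate variable.
#' @param n_bins Number of bins (default 50).
#' @param margin Fractional range expansion on each side (default 0.02).
#' @param range Optional explicit `c(lo, hi)` overriding the data range.
#' @return List with `breaks` (length `n_bins + 1`) and `centers`.
#' @export
niche_axis <- function(values, n_bins = 50, margin = 0.02, range = NULL) {
  if (is.null(range)) {
    r <- base::range(values)
    pad <- margin * diff(r)
    if (pad == 0) pad <- max(1e-8, abs(r[1]) * 1e-8 + 1e-8)
    range <- c(r[1] - pad, r[2] + pad)
  }
  breaks <- seq(range[1], range[2], length.out = n_bins + 1)
  list(breaks = breaks, centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
       n_bins = n_bins)
}

#' Bin county populations onto a 2-D climate grid
#'
#' Each county's population is added to exactly one cell. Cells are
#' half-open `[lo, hi)` with the final cell closed, so a county exactly on
#' an interior edge goes to the upper cell. The grid total equals the summed
#' population of in-range counties.
#'
#' @param c1,c2 County coordinates in climate space (e.g. annual temperature
#'   and temperature seasonality).
#' @param population County populations.
#' @param axis1,axis2 Axes from [niche_axis()].
#' @param out_of_range `"error"` (default) or `"drop"`.
#' @return `n_bins x n_bins` matrix of summed population (axis1 indexes rows).
#' @export
bin_population <- function(c1, c2, population, axis1, axis2,
                           out_of_range = c("error", "drop")) {
  out_of_range <- match.arg(out_of_range)
  i1 <- findInterval(c1, axis1$breaks, rightmost.closed = TRUE)
  i2 <- findInterval(c2, axis2$breaks, rightmost.closed = TRUE)
  ok <- i1 >= 1 & i1 <= axis1$n_bins & i2 >= 1 & i2 <= axis2$n_bins
  if (!all(ok)) {
    if (out_of_range == "error") {
      stop_domain(sum(!ok), " counties fall outside the binning axes")
    }
    i1 <- i1[ok]; i2 <- i2[ok]; population <- population[ok]
  }
  grid <- matrix(0, axis1$n_bins, axis2$n_bins)
  cell <- cbind(i1, i2)
  for (k in seq_along(population)) {
    grid[cell[k, 1], cell[k, 2]] <- grid[cell[k, 1], cell[k, 2]] + population[k]
  }
  grid
}

#' LOESS-smoothed log-abundance surface
#'
#' Fits a local quadratic (LOESS, tricube weights, span `alpha`) to
#' `log10(1 + population)` over the grid-cell centres and evaluates the fit
#' at every cell, yielding the smoothed realized-niche surface. The +1
#' offset keeps empty cells finite on the log scale. With fewer than 6
#' cells in a neighbourhood a quadratic is unidentifiable, so the degree is
#' lowered with a warning.
#'
#' @param grid Raw population grid from [bin_population()].
#' @param axis1,axis2 The axes that built the grid.
#' @param alpha Smoothing parameter in (0, 1]: fraction of cells in each
#'   local neighbourhood (default 0.3).
#' @param degree Local polynomial degree (default 2).
#' @return Object of class `"niche_surface"`: list with `raw`, `smooth`
#'   (matrices), `axis1`, `axis2`, `alpha`, `degree`, and `peaks` (filled by
#'   [find_peaks()], initially `NULL`).
#' @export
loess_surface <- function(grid, axis1, axis2, alpha = 0.3, degree = 2) {
  if (!(alpha > 0 && alpha <= 1)) stop_domain("alpha must be in (0, 1]")
  ncell <- length(grid)
  k <- ceiling(alpha * ncell)
  if (k < 6 && degree == 2) {
    warning("fewer than 6 cells per neighbourhood: lowering LOESS degree to 1",
            call. = FALSE)
    degree <- 1
  }
  dat <- expand.grid(u = axis1$centers, v = axis2$centers)
  dat$z <- as.vector(log10(1 + grid))
  ## On a regular grid both axes have identical index distributions, so
  ## loess' internal normalisation is equivalent to a nearest-cells metric.
  fit <- stats::loess(z ~ u + v, data = dat, span = alpha, degree = degree,
                      family = "gaussian", surface = "direct", normalize = TRUE)
  smooth <- matrix(stats::fitted(fit), nrow(grid), ncol(grid))
  if (any(!is.finite(smooth))) stop_domain("non-finite values in smoothed surface")
  structure(list(raw = grid, smooth = smooth, axis1 = axis1, axis2 = axis2,
                 alpha = alpha, degree = degree, peaks = NULL),
            class = "niche_surface")
}

#' @export
print.niche_surface <- function(x, ...) {
  cat(sprintf("Niche surface: %d x %d grid, alpha = %.2f, degree = %d\n",
              nrow(x$raw), ncol(x$raw), x$alpha, x$degree))
  cat(sprintf("Total binned population: %.6g\n", sum(x$raw)))
  if (!is.null(x$peaks) && nrow(x$peaks)) {
    cat("Peaks:\n"); print(x$peaks, row.names = FALSE)
  }
  invisible(x)
}

#' Local maxima of a smoothed surface
#'
#' Finds strict local maxima over 8-cell neighbourhoods (edge cells compare
#' against their available neighbours), drops those below `min_height`, and
#' greedily thins the rest so no two retained peaks lie within
#' `min_separation` cells of each other (the higher peak wins). Peaks are
#' returned sorted by height, highest first.
#'
#' @param surface A `"niche_surface"` or a numeric matrix.
#' @param min_separation Minimum Euclidean cell distance between peaks.
#' @param min_height Minimum smoothed value (default `-Inf`).
#' @return Data frame `row`, `col`, `c1`, `c2` (cell-centre climate
#'   coordinates when axes are known), `height`. May be empty.
#' @export
find_peaks <- function(surface, min_separation = 5, min_height = -Inf) {
  m <- if (inherits(surface, "niche_surface")) surface$smooth else surface
  nr <- nrow(m); nc <- ncol(m)
  cand <- NULL
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- m[i, j]
      if (v < min_height) next
      rs <- max(1, i - 1):min(nr, i + 1)
      cs <- max(1, j - 1):min(nc, j + 1)
      nb <- m[rs, cs, drop = FALSE]
      ## strict maximum: greater than every neighbour (self excluded once)
      self <- (match(j, cs) - 1L) * length(rs) + match(i, rs)
      vals <- as.vector(nb)[-self]
      if (length(vals) == 0L || v > max(vals)) {
        cand <- rbind(cand, c(i, j, v))
      }
    }
  }
  if (is.null(cand)) cand <- matrix(numeric(0), 0, 3)
  cand <- cand[order(-cand[, 3]), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  if (nrow(cand) > 1) {
    for (a in seq_len(nrow(cand))) {
      if (!keep[a]) next
      for (b in seq_len(nrow(cand))) {
        if (b <= a || !keep[b]) next
        d <- sqrt(sum((cand[a, 1:2] - cand[b, 1:2])^2))
        if (d < min_separation) keep[b] <- FALSE
      }
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(row = cand[, 1], col = cand[, 2],
                    c1 = NA_real_, c2 = NA_real_, height = cand[, 3])
  if (inherits(surface, "niche_surface")) {
    out$c1 <- surface$axis1$centers[out$row]
    out$c2 <- surface$axis2$centers[out$col]
  }
  out
}

#' Track niche peaks across censuses and sum abundance around them
#'
#' Matches peaks across years by nearest neighbour in cell coordinates
#' within `radius`; a peak with no lineage within the radius starts a new
#' lineage (reported via `message`). Per year and lineage, abundance is the
#' raw population summed over cells within `radius` of the matched peak.
#'
#' @param surfaces Named list (by census year, in time order) of
#'   `"niche_surface"` objects whose `peaks` element is filled (a data frame
#'   from [find_peaks()]).
#' @param radius Matching and summation radius in cells (default 5).
#' @return Object of class `"peak_lineages"`: list with `abundance` (lineage
#'   x year matrix, `NA` where unmatched) and `positions` (long data frame).
#' @export
track_peaks <- function(surfaces, radius = 5) {
  years <- names(surfaces)
  if (is.null(years)) years <- as.character(seq_along(surfaces))
  lineages <- list()  # each: list(row, col)
  pos <- NULL
  ab <- NULL
  cell_sum <- function(surf, r0, c0) {
    nr <- nrow(surf$raw); nc <- ncol(surf$raw)
    ii <- matrix(seq_len(nr), nr, nc)
    jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    sum(surf$raw[(ii - r0)^2 + (jj - c0)^2 <= radius^2])
  }
  for (t in seq_along(surfaces)) {
    surf <- surfaces[[t]]
    pk <- surf$peaks
    if (is.null(pk) || nrow(pk) == 0L) stop_domain("no peaks for year ", years[t])
    assigned <- rep(NA_integer_, nrow(pk))
    if (length(lineages)) {
      ## greedy by peak height: each peak claims nearest free lineage in range
      taken <- rep(FALSE, length(lineages))
      for (p in seq_len(nrow(pk))) {
        d <- vapply(lineages, function(L)
          sqrt((L$row - pk$row[p])^2 + (L$col - pk$col[p])^2), numeric(1))
        d[taken] <- Inf
        if (any(d <= radius)) {
          assigned[p] <- which.min(d)
          taken[assigned[p]] <- TRUE
        }
      }
    }
    for (p in seq_len(nrow(pk))) {
      if (is.na(assigned[p])) {
        lineages[[length(lineages) + 1L]] <- list(row = pk$row[p], col = pk$col[p])
        assigned[p] <- length(lineages)
        if (t > 1) message("new peak lineage started in year ", years[t])
      } else {
        lineages[[assigned[p]]] <- list(row = pk$row[p], col = pk$col[p])
      }
      pos <- rbind(pos, data.frame(
        year = years[t], lineage = assigned[p], row = pk$row[p],
        col = pk$col[p], height = pk$height[p],
        abundance = cell_sum(surf, pk$row[p], pk$col[p]),
        stringsAsFactors = FALSE
      ))
    }
  }
  nlin <- length(lineages)
  ab <- matrix(NA_real_, nlin, length(surfaces),
               dimnames = list(paste0("peak", seq_len(nlin)), years))
  for (r in seq_len(nrow(pos))) {
    ab[pos$lineage[r], pos$year[r]] <- pos$abundance[r]
  }
  structure(list(abundance = ab, positions = pos, radius = radius),
            class = "peak_lineages")
}

#' @export
print.peak_lineages <- function(x, ...) {
  cat(sprintf("Peak lineages (radius %.1f cells):\n", x$radius))
  print(x$abundance)
  invisible(x)
}
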