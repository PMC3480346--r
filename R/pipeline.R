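## End-to-end orchestration: synthetic or file-based inputs through climate
## normals, growth table, exposure accounting, niche surfaces and the GWR
## model suite, with CSV outputs and a JSON manifest.

#' Pipeline configuration
#'
#' Collects and validates every knob of an end-to-end run. Defaults mirror
#' the reference analysis: censuses 1900-2000 every 20 years, adaptive
#' bi-square GWR with fraction 0.3 (non-climate model raised to 0.5, 0.5
#' and 0.45 for the first three intervals, where spatial collinearity among
#' the socio-economic predictors is strongest), LOESS alpha 0.3 with
#' degree-2 polynomials, a 50 x 50 niche grid, and IDW power 2.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param synth A [synth_config()] (synthetic mode).
#' @param paths Named list with `counties` and `monthly` CSV paths (files
#'   mode).
#' @param census_years Census years (default from `synth`, else 1900-2000).
#' @param endpoints Years between which exposure deltas are computed
#'   (default `c(1920, 2000)` when available).
#' @param fraction Baseline adaptive fraction for GWR models.
#' @param nc_fractions Per-interval fractions for the non-climate GWR model.
#' @param loess_alpha,loess_degree Niche smoothing parameters.
#' @param grid_bins Niche grid resolution per axis.
#' @param idw_power IDW exponent.
#' @param niche_variables The two climate axes of the niche surface.
#' @param min_separation,track_radius Peak thinning and tracking radii
#'   (cells).
#' @param min_peak_height Minimum smoothed log10 abundance for a peak
#'   (default 1, i.e. at least ~9 persons per cell: suppresses the
#'   numerically tiny edge maxima LOESS can produce over empty climate
#'   space).
#' @param growth_method Growth-rate form.
#' @param seed Seed (synthetic mode; defaults to the synth config's).
#' @param out_dir Output directory.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            synth = synth_config(),
                            paths = NULL,
                            census_years = NULL,
                            endpoints = NULL,
                            fraction = 0.3,
                            nc_fractions = NULL,
                            loess_alpha = 0.3,
                            loess_degree = 2,
                            grid_bins = 50,
                            idw_power = 2,
                            niche_variables = c("annual_temp", "temp_seasonality"),
                            min_separation = 5,
                            track_radius = 5,
                            min_peak_height = 1,
                            growth_method = c("log", "geometric"),
                            seed = NULL,
                            out_dir = tempfile("gwrniche_run_")) {
  mode <- match.arg(mode)
  growth_method <- match.arg(growth_method)
  if (mode == "synthetic") {
    if (is.null(census_years)) census_years <- synth$census_years
    if (!identical(census_years, synth$census_years)) {
      stop_domain("configuration error: census_years must match the synthetic config")
    }
    if (is.null(seed)) seed <- synth$seed
  } else {
    if (is.null(paths) || !all(c("counties", "monthly") %in% names(paths))) {
      stop_domain("configuration error: files mode needs paths$counties and paths$monthly")
    }
    if (is.null(census_years)) census_years <- seq(1900, 2000, by = 20)
    if (is.null(seed)) seed <- 1L
  }
  assign_horizon(census_years, census_years)  # validates the census set
  K <- length(census_years) - 1
  if (is.null(endpoints)) {
    endpoints <- if (all(c(1920, 2000) %in% census_years)) c(1920, 2000)
    else range(census_years[-1])
  }
  if (!all(endpoints %in% census_years)) {
    stop_domain("configuration error: endpoint years not in census_years")
  }
  if (is.null(nc_fractions)) {
    nc_fractions <- rep(fraction, K)
    ov <- c(0.5, 0.5, 0.45)
    nc_fractions[seq_len(min(3, K))] <- ov[seq_len(min(3, K))]
  }
  if (length(nc_fractions) != K) {
    stop_domain("configuration error: nc_fractions must have one entry per interval")
  }
  fr <- c(fraction, nc_fractions, loess_alpha)
  if (any(fr <= 0 | fr > 1)) {
    stop_domain("configuration error: fractions and alpha must lie in (0, 1]")
  }
  structure(list(mode = mode, synth = synth, paths = paths,
                 census_years = census_years, endpoints = endpoints,
                 fraction = fraction, nc_fractions = nc_fractions,
                 loess_alpha = loess_alpha, loess_degree = loess_degree,
                 grid_bins = grid_bins, idw_power = idw_power,
                 niche_variables = niche_variables,
                 min_separation = min_separation, track_radius = track_radius,
                 min_peak_height = min_peak_height,
                 growth_method = growth_method, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: county filtering, station and county climate normals,
#' growth-table assembly, exposure/area trajectories, per-census niche
#' surfaces with peak detection and tracking, the four-model regression
#' suite per interval, and the relative-importance summary; writes every
#' stage's output as CSV plus a JSON manifest, and returns the in-memory
#' results invisibly. Identical config and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) list with elements `config`, `paths`, `counties`,
#'   `normals`, `growth`, `trajectory`, `surfaces`, `lineages`, `models`,
#'   `importance`, and `truth` (synthetic mode).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    stop_domain("configuration error: not a pipeline_config")
  }
  years <- config$census_years
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_domain("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  if (config$mode == "synthetic") {
    bundle <- stage("simulate", synth_dataset(config$synth))
    counties <- bundle$counties
    monthly <- bundle$monthly
    truth <- bundle$truth
  } else {
    counties <- stage("read", read_counties(config$paths$counties))
    monthly <- stage("read", utils::read.csv(config$paths$monthly,
                                             stringsAsFactors = FALSE))
    truth <- NULL
  }

  counties <- stage("filter", filter_complete_counties(counties, years))
  st_norm <- stage("normals", climate_normals(monthly, years))
  normals <- stage("normals", county_climate(st_norm, counties,
                                             power = config$idw_power))
  growth <- stage("growth", build_growth_table(counties, normals, years,
                                               method = config$growth_method))

  pops <- do.call(rbind, lapply(years, function(yr) {
    data.frame(county_id = counties$county_id, census_year = yr,
               population = counties[[paste0("pop_", yr)]],
               stringsAsFactors = FALSE)
  }))
  traj <- stage("exposure", exposure_trajectory(
    normals, pops, years, variables = config$niche_variables,
    endpoints = config$endpoints))

  ## Common axes across censuses so surfaces and peaks are comparable.
  v1 <- config$niche_variables[1]; v2 <- config$niche_variables[2]
  ax1 <- niche_axis(normals[[v1]], n_bins = config$grid_bins)
  ax2 <- niche_axis(normals[[v2]], n_bins = config$grid_bins)
  surfaces <- stage("niche", {
    out <- list()
    for (yr in years) {
      cli <- normals[normals$census_year == yr, , drop = FALSE]
      cli <- cli[match(counties$county_id, cli$county_id), , drop = FALSE]
      grid <- bin_population(cli[[v1]], cli[[v2]],
                             counties[[paste0("pop_", yr)]], ax1, ax2)
      surf <- loess_surface(grid, ax1, ax2, alpha = config$loess_alpha,
                            degree = config$loess_degree)
      surf$peaks <- find_peaks(surf, min_separation = config$min_separation,
                               min_height = config$min_peak_height)
      out[[as.character(yr)]] <- surf
    }
    out
  })
  lineages <- if (all(vapply(surfaces, function(s) nrow(s$peaks) > 0, logical(1)))) {
    stage("niche", track_peaks(surfaces, radius = config$track_radius))
  } else {
    message("run_pipeline: no peaks above threshold in some census; skipping peak tracking")
    NULL
  }

  coords_of <- function(ids) {
    as.matrix(counties[match(ids, counties$county_id), c("x", "y")])
  }
  intervals <- cbind(years[-length(years)], years[-1])
  models <- list()
  importance <- list()
  stdbeta <- list()
  for (k in seq_len(nrow(intervals))) {
    key <- paste(intervals[k, 1], intervals[k, 2], sep = "_")
    gk <- growth[growth$t0 == intervals[k, 1], , drop = FALSE]
    cmp <- stage(paste0("gwr ", key), compare_growth_models(
      gk, coords_of(gk$county_id),
      fractions = list(gwr_c = config$fraction,
                       gwr_nc = config$nc_fractions[k],
                       gwr_cnc = config$fraction)))
    models[[key]] <- cmp
    sb <- coef(attr(cmp, "fits")$gwr_cnc)
    sb <- sb[, colnames(sb) != "(Intercept)", drop = FALSE]
    stdbeta[[key]] <- data.frame(county_id = gk$county_id,
                                 t0 = intervals[k, 1], t1 = intervals[k, 2],
                                 sb, check.names = FALSE,
                                 stringsAsFactors = FALSE)
    importance[[key]] <- relative_importance(sb)
  }

  ## Outputs ---------------------------------------------------------------
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(config$out_dir, ...)
  paths <- c(growth_table = fp("growth_table.csv"),
             climate_normals = fp("climate_normals.csv"),
             exposure_trajectory = fp("exposure_trajectory.csv"),
             exposure_deltas = fp("exposure_deltas.csv"),
             niche_peaks = fp("niche_peaks.csv"),
             peak_abundance = fp("peak_abundance.csv"),
             model_comparison = fp("model_comparison.csv"),
             relative_importance = fp("relative_importance.csv"),
             manifest = fp("manifest.json"))
  utils::write.csv(growth, paths["growth_table"], row.names = FALSE)
  utils::write.csv(normals, paths["climate_normals"], row.names = FALSE)
  utils::write.csv(traj$trajectory, paths["exposure_trajectory"], row.names = FALSE)
  utils::write.csv(traj$deltas, paths["exposure_deltas"], row.names = FALSE)

  peaks_tab <- do.call(rbind, lapply(names(surfaces), function(yr) {
    pk <- surfaces[[yr]]$peaks
    if (nrow(pk)) cbind(census_year = yr, pk) else NULL
  }))
  if (is.null(peaks_tab)) {
    peaks_tab <- data.frame(census_year = character(0), row = integer(0),
                            col = integer(0), c1 = numeric(0), c2 = numeric(0),
                            height = numeric(0))
  }
  utils::write.csv(peaks_tab, paths["niche_peaks"], row.names = FALSE)
  ab <- if (is.null(lineages)) {
    data.frame(lineage = character(0))
  } else {
    data.frame(lineage = rownames(lineages$abundance), lineages$abundance,
               check.names = FALSE)
  }
  utils::write.csv(ab, paths["peak_abundance"], row.names = FALSE)
  for (yr in names(surfaces)) {
    p <- fp(paste0("niche_surface_", yr, ".csv"))
    utils::write.csv(surfaces[[yr]]$smooth, p, row.names = FALSE)
    paths[paste0("niche_surface_", yr)] <- p
  }
  cmp_tab <- do.call(rbind, lapply(names(models), function(key) {
    cbind(interval = key, as.data.frame(models[[key]]))
  }))
  utils::write.csv(cmp_tab, paths["model_comparison"], row.names = FALSE)
  for (key in names(stdbeta)) {
    p <- fp(paste0("stdbeta_", key, ".csv"))
    utils::write.csv(stdbeta[[key]], p, row.names = FALSE)
    paths[paste0("stdbeta_", key)] <- p
  }
  imp_tab <- do.call(rbind, lapply(names(importance), function(key) {
    im <- importance[[key]]
    data.frame(interval = key, predictor = names(im$proportion),
               proportion = as.numeric(im$proportion),
               group = ifelse(names(im$proportion) %in% predictor_groups()$climate,
                              "climatic", "non-climatic"),
               ties = im$ties, stringsAsFactors = FALSE)
  }))
  utils::write.csv(imp_tab, paths["relative_importance"], row.names = FALSE)

  manifest <- list(
    package = "gwrniche",
    package_version = as.character(utils::packageVersion("gwrniche")),
    r_version = R.version.string,
    seed = config$seed, mode = config$mode,
    census_years = config$census_years, endpoints = config$endpoints,
    fraction = config$fraction, nc_fractions = config$nc_fractions,
    loess_alpha = config$loess_alpha, grid_bins = config$grid_bins,
    idw_power = config$idw_power, growth_method = config$growth_method,
    outputs = as.list(paths[names(paths) != "manifest"])
  )
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(config = config, paths = paths, counties = counties,
                 normals = normals, growth = growth, trajectory = traj,
                 surfaces = surfaces, lineages = lineages, models = models,
                 importance = importance, stdbeta = stdbeta, truth = truth))
}

#' Summarise a pipeline run
#'
#' Prints the endpoint exposure and area deltas with the amplification
#' ratio, each interval's top predictor and the climatic-group share of
#' counties, and the model Akaike weights.
#'
#' @param results The list returned by [run_pipeline()].
#' @return The printed summary lines, invisibly.
#' @export
summarize_run <- function(results) {
  need <- c("trajectory", "models", "importance")
  miss <- need[!need %in% names(results) |
                 vapply(need, function(f) is.null(results[[f]]), logical(1))]
  if (length(miss)) {
    stop_domain("incomplete results bundle; missing: ", paste(miss, collapse = ", "))
  }
  lines <- character(0)
  say <- function(fmt, ...) lines <<- c(lines, sprintf(fmt, ...))
  d <- results$trajectory$deltas
  for (i in seq_len(nrow(d))) {
    say("%s: exposure delta %.4g, area delta %.4g, amplification %s (%d-%d)",
        d$variable[i], d$delta_exposure[i], d$delta_area[i],
        if (d$amplification_defined[i]) sprintf("%.3g", d$amplification[i])
        else "undefined", d$from[i], d$to[i])
  }
  for (key in names(results$importance)) {
    im <- results$importance[[key]]
    top <- names(which.max(im$proportion))
    cli <- im$group_proportion[["climate"]]
    wt <- results$models[[key]]
    say("interval %s: top predictor %s (%.1f%% of counties), climatic share %.1f%%, GWR_C+NC weight %.4f",
        key, top, 100 * max(im$proportion), 100 * cli,
        wt$akaike_weight[wt$model == "GWR_C+NC"])
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
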