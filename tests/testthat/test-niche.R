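test_that("exposure and area means follow the weighting definitions", {
  expect_equal(exposure_mean(c(10, 20), c(1, 1)), 15)
  expect_equal(exposure_mean(c(10, 20), c(0, 5)), 20)
  expect_equal(exposure_mean(c(10, 20), c(1, 3)), 17.5)
  # invariant to uniform weight scaling
  expect_equal(exposure_mean(c(3, 9, 1), c(2, 5, 1)),
               exposure_mean(c(3, 9, 1), 1000 * c(2, 5, 1)))
  expect_error(exposure_mean(c(1, 2), c(0, 0)), "total weight")

  expect_equal(area_mean(c(10, 20)), 15)
  expect_equal(area_mean(7), 7)
  expect_error(area_mean(numeric(0)), "empty")
})

test_that("amplification ratio handles zero area change with a flag", {
  expect_equal(as.numeric(amplification_ratio(1.5, 0.24)), 6.25)
  expect_equal(as.numeric(amplification_ratio(0.3, 0.3)), 1)
  r <- amplification_ratio(0.5, 0)
  expect_true(is.na(r))
  expect_true(attr(r, "undefined"))
})

test_that("exposure trajectory matches the analytic amplification oracle", {
  cfg <- synth_config(n_side = 6, trend_per_year = 0,
                      census_years = seq(1900, 2000, 20))
  sc <- make_amplification_scenario(cfg, c_rate = 0.003)
  tr <- exposure_trajectory(sc$normals, sc$populations_long,
                            cfg$census_years, variables = "annual_temp",
                            endpoints = c(1920, 2000),
                            omit_area_years = integer(0))
  expect_equal(tr$trajectory$exposure_mean, sc$expected_exposure$exposure,
               tolerance = 1e-8)
  d <- tr$deltas
  expect_identical(d$delta_area, 0)       # climate frozen: exactly zero
  expect_gt(d$delta_exposure, 0)
  expect_false(d$amplification_defined)

  # populations swapped to favour cold counties flip the delta sign
  swapped <- sc$populations_long
  ord <- order(sc$temps)
  for (yr in unique(swapped$census_year)) {
    i <- swapped$census_year == yr
    p <- swapped$population[i]
    swapped$population[i][ord] <- p[ord][rev(seq_along(p))]
  }
  tr2 <- exposure_trajectory(sc$normals, swapped, cfg$census_years,
                             variables = "annual_temp", endpoints = c(1920, 2000),
                             omit_area_years = integer(0))
  expect_lt(tr2$deltas$delta_exposure, 0)

  # uniform populations: exposure equals area mean exactly
  unif <- sc$populations_long
  unif$population <- 1
  tr3 <- exposure_trajectory(sc$normals, unif, cfg$census_years,
                             variables = "annual_temp",
                             omit_area_years = integer(0))
  expect_identical(tr3$trajectory$exposure_mean, tr3$trajectory$area_mean)
  # constant climate + constant populations: all deltas zero
  expect_equal(tr3$deltas$delta_exposure, 0)
  expect_equal(tr3$deltas$delta_area, 0)
})

test_that("the area mean is flagged for census years sharing a horizon", {
  normals <- do.call(rbind, lapply(c(1900, 1920), function(yr) {
    data.frame(county_id = c("a", "b"), census_year = yr,
               annual_temp = c(10, 20))
  }))
  pops <- do.call(rbind, lapply(c(1900, 1920), function(yr) {
    data.frame(county_id = c("a", "b"), census_year = yr,
               population = c(1, yr - 1899))
  }))
  tr <- exposure_trajectory(normals, pops, c(1900, 1920),
                            variables = "annual_temp", endpoints = c(1900, 1920))
  expect_true(is.na(tr$trajectory$area_mean[tr$trajectory$census_year == 1900]))
  expect_false(is.na(tr$trajectory$area_mean[tr$trajectory$census_year == 1920]))
})

test_that("exposure change decomposes into climate and demographic parts", {
  set.seed(4)
  ca <- rnorm(50, 10); pa <- rlnorm(50); pb <- rlnorm(50)
  # uniform climate shift: components sum to the total (zero cross term)
  cb <- ca + 0.7
  d <- exposure_decomposition(ca, cb, pa, pb)
  expect_equal(d$climate_component + d$demographic_component, d$total,
               tolerance = 1e-12)
  expect_equal(d$climate_component, 0.7, tolerance = 1e-12)
  # frozen populations isolate the climate part; frozen climate the demographic
  d2 <- exposure_decomposition(ca, cb, pa, pa)
  expect_equal(d2$total, d2$climate_component, tolerance = 1e-12)
  d3 <- exposure_decomposition(ca, ca, pa, pb)
  expect_equal(d3$total, d3$demographic_component, tolerance = 1e-12)
})

test_that("population binning conserves totals and uses half-open cells", {
  ax <- niche_axis(c(0, 10), n_bins = 5, margin = 0)
  g <- bin_population(2.5, 2.5, 100, ax, ax)
  expect_equal(sum(g), 100)
  expect_equal(sum(g > 0), 1)
  # two counties in the same cell are summed
  g2 <- bin_population(c(2.4, 2.6), c(2.4, 2.6), c(10, 20), ax, ax)
  expect_equal(max(g2), 30)
  # interior edge goes to the upper cell: breaks at 0,2,4,...
  g3 <- bin_population(4, 1, 7, ax, ax)
  expect_equal(which(rowSums(g3) > 0), 3)
  # top edge closed
  g4 <- bin_population(10, 10, 1, ax, ax)
  expect_equal(g4[5, 5], 1)
  # exact integer conservation on many random counties
  set.seed(2)
  c1 <- runif(400, 0, 10); c2 <- runif(400, 0, 10)
  pop <- rpois(400, 50)
  expect_identical(sum(bin_population(c1, c2, pop, ax, ax)), as.numeric(sum(pop)))
  expect_error(bin_population(11, 5, 1, ax, ax), "outside")
  expect_equal(sum(bin_population(c(11, 5), c(5, 5), c(1, 2), ax, ax,
                                  out_of_range = "drop")), 2)
})

test_that("LOESS surface reproduces constants and locates a single bump", {
  ax <- niche_axis(c(0, 10), n_bins = 10, margin = 0)
  const <- matrix(99, 10, 10)
  s <- loess_surface(const, ax, ax, alpha = 0.5)
  expect_equal(s$smooth, matrix(log10(100), 10, 10), tolerance = 1e-9)

  bi <- bimodal_grid(n_bins = 20, mass2 = 0)  # single bump at (8, 8)
  s1 <- loess_surface(bi$grid, bi$ax1, bi$ax2, alpha = 0.3, degree = 2)
  am <- which(s1$smooth == max(s1$smooth), arr.ind = TRUE)
  expect_lte(max(abs(am - c(cell_of(bi$ax1, 8), cell_of(bi$ax2, 8)))), 1)
  expect_true(all(is.finite(s1$smooth)))

  # oversmoothing with alpha = 1 lowers the peaks of a bimodal field
  bi2 <- bimodal_grid()
  s03 <- loess_surface(bi2$grid, bi2$ax1, bi2$ax2, alpha = 0.3)
  s10 <- loess_surface(bi2$grid, bi2$ax1, bi2$ax2, alpha = 1)
  expect_lt(max(s10$smooth), max(s03$smooth))

  expect_error(loess_surface(const, ax, ax, alpha = 0), "alpha")
  # tiny grids cannot support a local quadratic: degree is lowered, loudly
  w <- testthat::capture_warnings(
    loess_surface(matrix(c(1, 2, 3, 4), 2, 2),
                  niche_axis(c(0, 1), 2, 0), niche_axis(c(0, 1), 2, 0),
                  alpha = 1))
  expect_true(any(grepl("lowering LOESS degree", w)))
})

test_that("peak finding returns the two bump cells and thins close pairs", {
  bi <- bimodal_grid()
  s <- loess_surface(bi$grid, bi$ax1, bi$ax2, alpha = 0.3, degree = 2)
  pk <- find_peaks(s, min_separation = 5, min_height = 1)
  expect_equal(nrow(pk), 2)
  expect_lte(max(abs(pk[1, c("row", "col")] -
                       c(cell_of(bi$ax1, 8), cell_of(bi$ax2, 8)))), 1)
  expect_lte(max(abs(pk[2, c("row", "col")] -
                       c(cell_of(bi$ax1, 22), cell_of(bi$ax2, 21)))), 1)
  expect_true(all(diff(pk$height) <= 0))  # sorted by height

  # a monotone plane has no interior peaks
  plane <- outer(1:15, 1:15, function(i, j) i + 2 * j)
  pkp <- find_peaks(plane, min_separation = 2)
  interior <- pkp$row > 1 & pkp$row < 15 & pkp$col > 1 & pkp$col < 15
  expect_equal(sum(interior), 0)

  # two bumps closer than min_separation collapse to the higher one
  near <- bimodal_grid(center1 = c(10, 10), center2 = c(14, 14))
  sn <- loess_surface(near$grid, near$ax1, near$ax2, alpha = 0.3)
  pkn <- find_peaks(sn, min_separation = 10, min_height = 1)
  expect_equal(nrow(pkn), 1)
})

test_that("peak tracking follows lineages and sums abundance around them", {
  mk <- function(scale2) {
    bi <- bimodal_grid(mass1 = 1e5, mass2 = 6e4 * scale2)
    s <- loess_surface(bi$grid, bi$ax1, bi$ax2, alpha = 0.3)
    s$peaks <- find_peaks(s, min_separation = 5, min_height = 1)
    s
  }
  surfaces <- list("1900" = mk(1), "1920" = mk(1.6), "1940" = mk(2.5))
  tl <- track_peaks(surfaces, radius = 4)
  expect_equal(nrow(tl$abundance), 2)
  # the cool bump is static, the warm one grows
  grow <- which.max(tl$abundance[, "1940"] / tl$abundance[, "1900"])
  expect_true(all(diff(tl$abundance[grow, ]) > 0))
  flat <- setdiff(1:2, grow)
  expect_equal(tl$abundance[flat, "1940"], tl$abundance[flat, "1900"],
               tolerance = 1e-4)

  # identical surfaces give constant series
  same <- list("1900" = mk(1), "1920" = mk(1))
  tls <- track_peaks(same, radius = 4)
  expect_equal(tls$abundance[, 1], tls$abundance[, 2])

  # a peak drifting within the radius stays one lineage
  drift <- list("1900" = mk(1), "1920" = mk(1))
  drift[["1920"]]$peaks$row <- drift[["1920"]]$peaks$row + 1
  tld <- track_peaks(drift, radius = 4)
  expect_equal(nrow(tld$abundance), 2)
  expect_false(anyNA(tld$abundance))
})
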