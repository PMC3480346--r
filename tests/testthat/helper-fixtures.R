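# Shared fixtures, built in code.

# Small synthetic bundle: 8x8 lattice, three censuses, default surfaces.
small_bundle <- function(seed = 3, n_side = 8, noise_sd = 0.01) {
  synth_dataset(synth_config(n_side = n_side, seed = seed,
                             noise_sd = noise_sd,
                             census_years = seq(1900, 1940, by = 20)))
}

# Growth table plus aligned coordinates for one interval of a bundle.
interval_fixture <- function(bundle, t0 = 1900) {
  g <- build_growth_table(bundle$counties, bundle$county_normals,
                          bundle$config$census_years,
                          method = bundle$config$growth_method)
  g <- g[g$t0 == t0, , drop = FALSE]
  coords <- as.matrix(bundle$counties[match(g$county_id, bundle$counties$county_id),
                                      c("x", "y")])
  list(growth = g, coords = coords)
}

# Bimodal population field over a climate-space grid: two Gaussian bumps.
bimodal_grid <- function(n_bins = 20, center1 = c(8, 8), center2 = c(22, 21),
                         mass1 = 1e5, mass2 = 6e4, sd = 3) {
  ax1 <- niche_axis(c(0, 30), n_bins = n_bins, margin = 0)
  ax2 <- niche_axis(c(0, 30), n_bins = n_bins, margin = 0)
  u <- expand.grid(c1 = ax1$centers, c2 = ax2$centers)
  pop <- mass1 * exp(-((u$c1 - center1[1])^2 + (u$c2 - center1[2])^2) / (2 * sd^2)) +
    mass2 * exp(-((u$c1 - center2[1])^2 + (u$c2 - center2[2])^2) / (2 * sd^2))
  list(grid = bin_population(u$c1, u$c2, pop, ax1, ax2),
       ax1 = ax1, ax2 = ax2, center1 = center1, center2 = center2)
}

# Nearest cell index of a climate coordinate on an axis.
cell_of <- function(axis, value) which.min(abs(axis$centers - value))
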