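# gwrniche

Climate-correlated demographic change on a county lattice: who lives where
in climate space, how population growth redistributes people across that
space, and how strongly climatic versus socio-economic conditions correlate
with growth — with explicit attention to spatial non-stationarity.

The package is aimed at spatial demographers, biogeographers and
climate-impact researchers who work with county-resolution census tables
and interpolated station climatologies, and at anyone who needs a compact,
fully testable geographically weighted regression (GWR) implementation in
base R.

## What it computes

**Growth rates and predictors.** For censuses every 20 years, the annual
growth rate of human population density over an interval \[t0, t1\] is

    lambda = ln( hd(t1) / hd(t0) ) / (t1 - t0),

which depends only on the density ratio, so it is mathematically
independent of the density level (a geometric-rate variant is available).
Each interval's predictors are the four climate normals at the interval
start — mean annual temperature (°C), temperature seasonality (SD of the
12 monthly means, °C), total annual precipitation (mm), precipitation
seasonality (mm) — plus log10 density, a within-census income z-score,
arc-sine-square-root agricultural density, and square-root waterway
distance. Climate normals are 20-year averages of yearly station summaries,
interpolated to county centroids by inverse-distance weighting.

**Exposure vs climate change.** The population-weighted mean of a climate
variable ("climate exposure", the climate experienced by the average
person) is tracked against the unweighted county mean ("climate change").
Their endpoint changes and the ratio delta_exposure / delta_area quantify
*demographic amplification*: exposure moving faster than the climate
because growth concentrates in particular climates.

**The realized climate niche.** County populations are binned on a 2-D
climate grid (annual temperature × temperature seasonality), smoothed as
log10(1 + population) with 2-D LOESS (degree-2 local polynomials, tricube
weights, alpha = 0.3), and the surface's peaks are detected, thinned and
tracked across censuses.

**Geographically weighted regression.** One weighted least-squares model
per county,

    beta(i) = (X' W_i X)^{-1} X' W_i y,

with an adaptive bi-square kernel w = (1 - (d/b)^2)^2 whose bandwidth b is
the distance to a fixed fraction (default 30%) of neighbouring counties.
The fit reports per-location standardized coefficients (stdβ), the hat
diagonal, effective parameters enp = tr(S), and the small-sample AICc
`n log(RSS/n) + n log(2π) + n (n + enp)/(n - 2 - enp)`. A four-model suite
(global OLS, GWR with climate-only, non-climate-only, and all predictors)
is compared by AICc/Akaike weights, and predictor importance is the share
of counties where a predictor has the largest |stdβ|.

A seeded synthetic-data module generates the whole input set — county
lattice, monthly climate series, skewed covariates, census histories — from
known coefficient surfaces, so every stage can be validated against ground
truth without external data.

## Worked example

```r
library(gwrniche)

cfg    <- synth_config(n_side = 12, seed = 42)      # 144 synthetic counties
bundle <- synth_dataset(cfg)
growth <- build_growth_table(bundle$counties, bundle$county_normals,
                             cfg$census_years)

g1     <- growth[growth$t0 == 1980, ]
coords <- bundle$counties[match(g1$county_id, bundle$counties$county_id),
                          c("x", "y")]
fit <- gwreg(lambda ~ annual_temp + temp_seasonality + log_density + income_z,
             g1, coords, fraction = 0.3, standardize = "xy")
summary(fit)
#> Geographically weighted regression
#> n = 144, bisquare kernel, fraction 0.30, bandwidth 3.61-7
#> Per-location coefficients:
#>                      Min      Q1  Median      Q3    Max
#> (Intercept)      -0.5198 -0.3739 -0.2670 -0.1293 0.1989
#> annual_temp       0.0216  0.2536  0.5411  0.7858 1.1046
#> temp_seasonality -0.4471 -0.2406 -0.0612  0.0916 0.4175
#> log_density      -0.1987 -0.0335  0.0390  0.2265 0.7404
#> income_z         -0.1506  0.0875  0.2753  0.4041 0.6393
#> enp 36.43, RSS 46.1396, sigma2 0.320414, R2 0.6773, AICc 346.87
```

The coefficient quartiles summarise *spatial* variation: here the
temperature stdβ is positive everywhere but three times stronger in some
regions than others — exactly the non-stationarity GWR exists to expose.
`enp` (36.4 effective parameters from 5 nominal ones) measures how much
local flexibility the kernel bought.

```r
traj <- exposure_trajectory(bundle$county_normals, bundle$populations_long,
                            cfg$census_years)
traj
#> Climate exposure vs area-averaged climate trajectory
#> Endpoint deltas (1920 -> 2000):
#>          variable from   to delta_exposure delta_area amplification
#>       annual_temp 1920 2000        1.03906  2.400e-01         4.329
#>  temp_seasonality 1920 2000       -0.04851 -8.882e-16            NA
```

The average synthetic citizen's temperature rose 1.04 °C while the
thermometer rose 0.24 °C — a 4.3× demographic amplification; seasonality
shows a pure demographic shift (area change at rounding level, flagged
undefined).

```r
ri <- relative_importance(coef(fit))
round(ri$group_proportion, 3)
#>    climate nonclimate
#>      0.646      0.354
```

64.6% of counties have a climate variable as their strongest growth
correlate in this interval.

`run_pipeline(pipeline_config(...))` chains every stage (filtering,
normals, growth table, exposure, niche surfaces and peaks, the GWR model
suite, relative importance) and writes each output as CSV plus a JSON
manifest; `summarize_run()` prints the headline numbers.

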