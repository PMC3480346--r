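---
title: "Methods: growth rates, climate exposure, niche surfaces and geographically weighted regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth rates, climate exposure, niche surfaces and geographically weighted regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwrniche)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the numerical choices made where a design was genuinely open.

## The demographic model

The unit of analysis is the county–interval. Over a census interval
$[t_0, t_1]$ the annual growth rate of human population density $hd$ is

$$\lambda = \frac{\ln\big(hd(t_1)/hd(t_0)\big)}{t_1 - t_0},$$

the continuous (instantaneous) annual rate. Because $\lambda$ depends only
on the density *ratio*, it is mathematically independent of the density
level, leaving any empirical density–growth correlation free to be
estimated rather than built in. A discrete geometric variant
$(hd_1/hd_0)^{1/\Delta t} - 1$ is available via `method = "geometric"`;
the two agree to first order in $\lambda \Delta t$ and both are
density-ratio functions, so the choice affects units of interpretation,
not the qualitative analysis. `project_density()` is the exact inverse of
`growth_rate()` under either form and is the single source of truth used
by the synthetic generator, which is why noiseless round-trip tests hold
to machine precision.

Counties enter the analysis only if they report a population at every
configured census (`filter_complete_counties()`), mirroring the standard
practice of restricting to stable-boundary counties when census geography
changes over time.

### Predictor transforms

Each interval's eight predictors are evaluated at the interval start:

* the four climate normals (below);
* $\log_{10}$ population density — county densities are strongly
  right-skewed;
* an income z-score computed *within* census (sample SD), which preserves
  geography while making inconsistently measured census income queries
  comparable across decades; censuses with no usable income query are
  interpolated from the flanking censuses with proximity weights (the
  historical 1960 interpolation uses 0.333/0.667 on the 1940/1970
  estimates, kept exactly as printed rather than as thirds), and censuses
  reporting only categorical income ranges are collapsed by
  count-weighted category midpoints;
* arc-sine square-root agricultural density (crop + pasture extent over
  land area), the classical variance-stabilising transform for fractions,
  with fractions clipped to $[0,1]$ against inconsistent source areas;
* square-root waterway distance, normalising a right-skewed distance
  distribution.

## Climate variables

From monthly station series, each station-year yields four summaries: the
mean of the 12 monthly temperatures, their standard deviation
(*temperature seasonality*), the summed monthly precipitation, and its
standard deviation (*precipitation seasonality*). Seasonality uses the
sample SD ($n-1$) by default; the population-SD option changes every value
by the same factor $\sqrt{11/12}$ and therefore nothing downstream that is
scale-free (z-scored designs, correlations). SDs are computed by a
two-pass (centred) algorithm: the one-pass $\sum x^2 - n\bar x^2$ form
loses enough precision on realistic magnitudes to turn
exactly-time-invariant seasonality fields into last-ulp noise.

Yearly summaries are averaged over each census's 20-year horizon — the 20
years preceding the census, with the first census sharing the earliest
available horizon when the instrumental record starts after it (1900 and
1920 both use 1901–1920). Station normals are interpolated to county
centroids by inverse-distance weighting, $w_i = d_i^{-p}$ with $p = 2$ by
default ($p$ is not pinned by any contract here; at stations the
interpolator is exact regardless of $p$, and all stations are used — no
cutoff radius). Distances are planar Euclidean in the input coordinates;
for geographic data in degrees this matches the convention of quoting
adaptive bandwidths in degrees.

## Climate exposure versus climate change

For a climate variable $c$ and county populations $p$,

$$E = \frac{\sum_i p_i c_i}{\sum_i p_i}$$

is the *exposure mean* — the climate experienced by the average person —
while the unweighted county mean is the *area mean*. Tracking both across
censuses separates two processes: the climate changing under a fixed
population, and the population redistributing across a fixed climate.
Their endpoint changes give the amplification ratio
$\Delta E / \Delta A$; values above 1 mean demography moved the average
citizen's climate faster than the climate itself moved.
`exposure_decomposition()` makes the split explicit by freezing each
factor in turn; the two components sum to the total exactly when the
cross term vanishes (e.g. under a spatially uniform climate shift), which
is asserted on fixtures rather than assumed in general.

Numerical conventions: uniform weights are detected and reduced to the
plain mean, so the exposure/area identity under equal populations is
exact in floating point; an area change below $10^{-9}$ of the variable's
magnitude is treated as zero and the ratio flagged undefined instead of
reporting an absurd quotient; and when two censuses share one climate
horizon the earlier census's area mean is reported as `NA` (it would
duplicate the later one) while its exposure mean remains informative
through the populations.

## The realized climate niche surface

County populations are binned on a 2-D grid over climate space (default
50 × 50, spanning the observed range plus a 2% margin; cells are
half-open $[lo, hi)$ with the last cell closed, so binning conserves total
population exactly). The binned abundance is smoothed as
$\log_{10}(1 + \text{population})$ — the offset keeps empty cells finite —
by 2-D LOESS with second-order local polynomials, tricube weights and
span $\alpha = 0.3$; smoothing uses `stats::loess` with
`surface = "direct"`, whose neighbour count is $\lfloor \alpha N \rfloor$
(one cell fewer than a ceiling rule at most — immaterial at these grid
sizes), and whose internal normalisation is equivalent to a nearest-cells
metric on a regular grid. Neighbourhoods too small for a quadratic
($< 6$ cells) trigger a degree reduction with a warning. The binning
resolution is a package choice: results at 40–60 bins are qualitatively
identical on the synthetic fixtures, consistent with the general
robustness of LOESS summaries to moderate resolution changes.

Peaks are strict local maxima over 8-cell neighbourhoods, greedily thinned
so no two retained peaks are within `min_separation` cells (the higher
wins), and tracked across censuses by nearest-neighbour matching within a
radius, with per-year abundance summed over cells within that radius. The
pipeline additionally requires a peak's smoothed value to reach 1 (about
nine persons per cell): LOESS over the mostly-empty corners of climate
space can ring by a few tenths of a log unit, and those wiggles are
maxima in the strict sense but not population concentrations.
`find_peaks()` itself defaults to no height threshold. Thinning,
tracking radius and threshold are all configurable; they are bookkeeping
conventions, not substantive claims.

## Geographically weighted regression

The growth model for an interval is a local linear regression at every
county $i$:

$$\hat\beta(i) = (X^{\top} W_i X)^{-1} X^{\top} W_i y,$$

with $W_i$ diagonal in the bi-square kernel
$w(d) = (1 - (d/b_i)^2)^2$ for $d < b_i$, zero beyond. The bandwidth is
*adaptive*: $b_i$ is the distance from county $i$ to its $k$-th nearest
other county, $k = \lceil f (n-1) \rceil$ with neighbour fraction
$f = 0.3$ by default ("30% of the neighbouring counties", read as
excluding the focal county). Adaptive bandwidths avoid the coastal/edge
bias of a fixed radius, where fewer neighbours would inflate variance.

Fits are reported on the z-scored design (`standardize = "xy"`): the
resulting stdβ are comparable in magnitude across predictors and
counties, which is what the relative-importance summary requires.
Standardisation is global per interval, not per-location — locally
re-standardised coefficients would not be comparable across space.
Raw-scale coefficients are recoverable exactly from the recorded scaling.

Diagnostics follow the linear-smoother view: the hat row of each local
fit gives the fitted value's weights; the trace of the hat matrix is the
*effective number of parameters* (enp), equal to the parameter count for
OLS and growing toward $n$ as bandwidths shrink; and model comparison
uses the small-sample AICc
$$\mathrm{AICc} = n\ln(\mathrm{RSS}/n) + n\ln(2\pi) +
  n\,\frac{n + \mathrm{enp}}{n - 2 - \mathrm{enp}},$$
applied with the same formula to OLS (enp = $p$) and GWR models so the
comparison is like-for-like; Akaike weights are
$e^{-\Delta_m/2} / \sum_k e^{-\Delta_k/2}$. The four-model suite fits
OLS with all eight predictors, GWR with the four climate predictors, GWR
with the four non-climate predictors, and GWR with all eight.

Numerical choices: local systems are solved by explicit normal equations
(the estimator's defining form) with a 1-norm condition-number guard at
$10^{10}$; a collinear local design aborts the fit and retries the whole
model at the next fallback fraction (0.45, then 0.5), mirroring the
practice of widening bandwidths when predictors are spatially collinear —
the default pipeline applies exactly such raised fractions (0.5, 0.5,
0.45) to the non-climate model in the first three intervals, where the
socio-economic predictors are most collinear. No ridge term is added: it
would change the estimator. Exact ties in the relative-importance vote go
to the first predictor in canonical column order and are counted
(a measure-zero event for continuous data); importance proportions are
formed from integer counts so they sum to one exactly.

Bandwidth selection by cross-validation or AICc minimisation is
deliberately out of scope: the analysis design fixes the neighbour
fractions, and the comparison of interest is between predictor sets at a
common kernel, not between bandwidths.

## The synthetic generator

The generator produces the complete input set with known truth:

* **Lattice.** $n^2$ counties on a unit grid, unit areas; stations
  coincide with centroids by default (making interpolation exact, a
  pipeline identity used in tests), with an optional offset to exercise
  nontrivial IDW.
* **Climate.** Monthly temperature is a smooth mean field plus a seasonal
  amplitude times $\sin(2\pi m/12)$ plus a linear trend; precipitation is
  analogous and floored at 0 for physical nonnegativity. Mean fields and
  amplitudes are linear gradients plus two optional smooth components — a
  Gaussian "orographic" bump and a low-amplitude sinusoidal mesoscale
  ripple. The extras exist for an identifiability reason: with purely
  planar fields, every derived climate variable is an exact plane over the
  lattice, and any local design containing several climate predictors plus
  an intercept is rank-deficient within a kernel window (exactly the
  spatial-collinearity failure that motivates raised bandwidths). The
  bump and ripple keep fields smooth but locally full-rank. Setting them
  to zero recovers the plain gradient-plus-seasonality field used in the
  closed-form tests.
* **Covariates.** Log-normal income (right-skewed), a noisy clipped
  gradient for agricultural fraction, and waterway distance to a
  designated lattice edge.
* **Populations.** Per interval,
  $\lambda_i = \beta_0(x_i,y_i) + \sum_j \beta_j(x_i,y_i)\, z_{ij} +
  \varepsilon_i$ with $\varepsilon \sim N(0, \sigma)$, where $z$ are the
  z-scored transformed predictors (the same quantities the growth table
  exposes, so estimated and true coefficient surfaces are directly
  comparable) and the $\beta$ surfaces are configurable constants,
  gradients or Gaussian bumps. Populations advance by the exact inverse of
  the growth-rate definition and are kept continuous, so noiseless
  round-trips are exact to $10^{-10}$ rather than limited by integer
  rounding.

**Reference conditions.** The defaults are one fixed choice of study
conditions: a 30 × 30 lattice (900 counties, the scale of the validation
fixtures), censuses 1900–2000 every 20 years, residual growth noise
$\sigma = 0.01\,\mathrm{yr}^{-1}$, baseline growth $0.013\,\mathrm{yr}^{-1}$
(a 20th-century national average scale), and a climate trend of
$0.003\,^{\circ}\mathrm{C\,yr^{-1}}$ (20th-century contiguous-US
magnitude). Default coefficient surfaces are *gentle* — contributions of
order $0.01\,\mathrm{yr}^{-1}$ per predictor with a positive mean
temperature effect — because effects much larger than this compound over a
century into degenerate demography (population mass collapsing onto a few
counties and exposure drifts of tens of degrees). The coefficient-recovery
validation fixture instead uses large-amplitude gradient and bump surfaces
(spread $\approx 0.05\,\mathrm{yr}^{-1}$): under its specified residual
noise of $0.05\,\mathrm{yr}^{-1}$, only spatial signal of that order is
measurable at all, and the fixture's purpose is estimator validation, not
demographic realism.

A separate engineered *amplification scenario* freezes the climate in
time and sets $\lambda_i = c\,T_i$, so the area mean is constant by
construction while the exposure mean follows the closed form
$E(t) = \sum_i T_i p_i(t) / \sum_i p_i(t)$, bundled as an analytic oracle.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: real census geography and boundary changes,
integer census rounding and undercount, spatially autocorrelated growth
residuals beyond the smooth coefficient surfaces, non-sinusoidal
seasonality, interannual climate variability (yearly fields are
deterministic given the trend), and measurement error in station series.
Tests demonstrate that the estimators recover what they are defined to
recover under known truth; they cannot certify behaviour under real-data
pathologies.

## Problem sizes and determinism

The test suite and the acceptance script run the estimator at the scales
of the validation fixtures: 900-county GWR fits, 400-county model-suite
comparisons, 50 × 50 niche grids — sizes at which every check completes
in seconds while leaving kernel neighbourhoods large enough to be
statistically meaningful. All randomness flows from a single integer seed
through a state-preserving wrapper, and every pipeline stage is a pure
function of its on-disk inputs, so identical configurations reproduce
byte-identical numeric CSVs.

## Known limitations

* IDW power and neighbourhood, LOESS binning resolution, peak-thinning
  and tracking radii are conventions; alternatives (kriging, kernel
  density estimates in climate space, watershed peak labelling) are out
  of scope.
* The AICc variant is one established GWR small-sample form; software
  packages differ in the exact correction, so absolute AICc values are
  comparable only within this package (weights and rankings are the
  meaningful outputs).
* The collinearity fallback raises the fraction for the *whole* model
  rather than per-location, keeping all local fits of one model at a
  common bandwidth at the cost of some local resolution.
* No inference (standard errors, Monte Carlo tests) on stdβ surfaces:
  the importance summary is descriptive.
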