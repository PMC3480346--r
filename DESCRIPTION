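Package: gwrniche
Title: Geographically Weighted Regression and Population-Weighted Climate
    Exposure for County Demographics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing climate-correlated demographic change on a
    county lattice. Computes census-interval growth rates of human population
    density and their transformed socio-economic covariates, derives annual
    temperature and precipitation means and seasonalities from monthly station
    series with inverse-distance interpolation to county centroids, quantifies
    population-weighted climate exposure against area-averaged climate change,
    maps the realized climate niche as a LOESS-smoothed abundance surface with
    peak detection and tracking, and fits geographically weighted regressions
    with adaptive bi-square kernels, effective-parameter counts, AICc model
    comparison and standardized-coefficient relative importance. A seeded
    synthetic-data generator with known coefficient surfaces supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
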