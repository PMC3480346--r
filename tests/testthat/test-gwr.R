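test_that("kernel weights match their closed forms", {
  expect_equal(bisquare_weight(0, 2), 1)
  expect_equal(bisquare_weight(2, 2), 0)
  expect_equal(bisquare_weight(1, 2), 0.5625)
  expect_equal(bisquare_weight(3, 2), 0)
  d <- seq(0, 1.5, by = 0.1)
  expect_true(all(diff(bisquare_weight(d, 1.5)) <= 0))
  expect_error(bisquare_weight(1, 0), "bandwidth")
  expect_equal(uniform_weight(c(0, 1, 2, 2.5), 2), c(1, 1, 1, 0))
})

test_that("adaptive bandwidth is the k-th nearest neighbour distance", {
  pts <- cbind(0:10, 0)
  expect_equal(adaptive_bandwidth(pts, 1, 0.3), 3)  # k = ceil(0.3*10) = 3
  expect_equal(adaptive_bandwidth(pts, 1, 1), 10)
  expect_equal(adaptive_bandwidth(cbind(c(0, 5), c(0, 0)), 1, 0.4), 5)
  expect_error(adaptive_bandwidth(pts, 1, 0), "fraction")
  expect_error(adaptive_bandwidth(rbind(c(0, 0), c(0, 0)), 1, 1), "duplicated")
})

test_that("local WLS matches an independent QR solve on random systems", {
  set.seed(99)
  for (rep in 1:100) {
    X <- cbind(1, matrix(rnorm(24), 12, 2))
    y <- rnorm(12)
    w <- runif(12, 0.05, 2)
    ours <- local_fit(X, y, w)$coefficients
    oracle <- qr.coef(qr(sqrt(w) * X), sqrt(w) * y)
    expect_equal(unname(ours), unname(oracle), tolerance = 1e-8)
  }
})

test_that("local WLS is exact for unit weights, exact data, and flags collinearity", {
  set.seed(5)
  X <- cbind(1, rnorm(30), runif(30))
  y <- drop(X %*% c(1, -2, 0.5))
  # unit weights reduce to OLS; exact linear data recovered exactly
  f <- local_fit(X, y + rnorm(30, 0, 0), rep(1, 30))
  expect_equal(unname(f$coefficients), c(1, -2, 0.5), tolerance = 1e-10)
  # weighted residual orthogonality X'W(y - Xb) = 0
  w <- runif(30)
  yn <- y + rnorm(30, 0, 0.3)
  b <- local_fit(X, yn, w)$coefficients
  expect_lt(max(abs(crossprod(X, w * (yn - drop(X %*% b))))), 1e-8)
  # collinear design raises a typed error
  Xc <- cbind(1, 1:30, 2 * (1:30))
  expect_error(local_fit(Xc, yn, w), class = "gwr_collinearity_error")
  expect_error(local_fit(X[1:2, ], y[1:2], c(1, 0)), "fewer positive weights")
})

test_that("GWR with a uniform full-window kernel reproduces global OLS", {
  set.seed(17)
  n <- 200
  d <- data.frame(x1 = rnorm(n), x2 = runif(n), u = runif(n), v = runif(n))
  d$y <- 0.5 + 1.5 * d$x1 - 2 * d$x2 + rnorm(n, 0, 0.2)
  fit <- gwreg(y ~ x1 + x2, d, d[c("u", "v")], fraction = 1, kernel = "uniform")
  ols <- coef(lm(y ~ x1 + x2, d))
  for (i in seq_len(n)) {
    expect_equal(unname(coef(fit)[i, ]), unname(ols), tolerance = 1e-8)
  }
  expect_equal(fit$enp, 3, tolerance = 1e-8)
})

test_that("GWR recovers constant coefficients exactly without noise", {
  set.seed(23)
  n <- 100
  d <- data.frame(x1 = rnorm(n), u = runif(n, 0, 10), v = runif(n, 0, 10))
  d$y <- 0.3 + 2 * d$x1
  fit <- gwreg(y ~ x1, d, d[c("u", "v")], fraction = 0.3)
  expect_lt(max(abs(coef(fit)[, "x1"] - 2)), 1e-6)
  expect_lt(max(abs(coef(fit)[, "(Intercept)"] - 0.3)), 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-6)
})

test_that("hat diagnostics behave like a linear smoother's", {
  set.seed(29)
  n <- 120
  d <- data.frame(x1 = rnorm(n), u = runif(n, 0, 10), v = runif(n, 0, 10))
  d$y <- 1 + d$x1 + rnorm(n, 0, 0.5)
  f2 <- gwreg(y ~ x1, d, d[c("u", "v")], fraction = 0.2)
  f9 <- gwreg(y ~ x1, d, d[c("u", "v")], fraction = 0.9)
  expect_true(all(f2$hat_diag >= 0 & f2$hat_diag <= 1))
  expect_gt(f2$enp, 2)
  expect_lt(f2$enp, n)
  expect_gt(f2$enp, f9$enp)  # enp decreases as the window widens
  expect_equal(effective_parameters(f2$hat_diag), f2$enp)
  expect_equal(effective_parameters(rep(1, 7)), 7)
})

test_that("GWR AICc and Akaike weights follow their formulas", {
  a1 <- gwr_aicc(10, 100, 5)
  expect_equal(gwr_aicc(10, 100, 5), a1)
  expect_equal(a1 - gwr_aicc(5, 100, 5), 100 * log(2))
  expect_gt(gwr_aicc(10, 100, 8), a1)  # penalty increases with enp
  expect_error(gwr_aicc(10, 10, 9), "enp")
  expect_error(gwr_aicc(0, 100, 5), "rss")

  expect_equal(akaike_weights(c(100, 100)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 110))
  expect_equal(w, c(1, exp(-5)) / (1 + exp(-5)))
  expect_equal(round(w, 4), c(0.9933, 0.0067))
  expect_equal(sum(akaike_weights(c(3, 8, 1, 40))), 1, tolerance = 1e-12)
  w2 <- akaike_weights(c(0, 200))
  expect_gt(w2[1], 1 - 1e-10)
})

test_that("design standardization round-trips coefficients to the raw scale", {
  set.seed(41)
  n <- 60
  d <- data.frame(annual_temp = rnorm(n, 10, 4), income_z = rnorm(n),
                  ag_density = runif(n))
  d$lambda <- 0.01 + 0.002 * d$annual_temp - 0.005 * d$income_z +
    0.01 * d$ag_density + rnorm(n, 0, 0.002)
  std <- standardize_design(d, "lambda",
                            c("annual_temp", "income_z", "ag_density"))
  expect_equal(unname(colMeans(std$X[, -1])), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(std$X[, -1], 2, sd)), rep(1, 3), tolerance = 1e-12)
  b_std <- local_fit(std$X, std$y, rep(1, n))$coefficients
  b_raw <- unstandardize_coef(b_std, std$scaling)
  oracle <- coef(lm(lambda ~ annual_temp + income_z + ag_density, d))
  expect_equal(unname(b_raw), unname(oracle), tolerance = 1e-10)

  d$dup <- 5
  expect_error(standardize_design(d, "lambda", c("annual_temp", "dup")),
               "zero-variance")
})

test_that("relative importance counts max-|stdbeta| votes with canonical ties", {
  sb <- rbind(c(0.5, 0.1, 0.2), c(0.1, 0.9, 0.2))
  colnames(sb) <- c("annual_temp", "income_z", "ag_density")
  ri <- relative_importance(sb, groups = list(climate = "annual_temp",
                                              nonclimate = c("income_z", "ag_density")))
  expect_equal(unname(ri$proportion), c(0.5, 0.5, 0))
  expect_equal(sum(ri$counts), ri$n)
  expect_equal(unname(ri$group_proportion), c(0.5, 0.5))
  # dominance
  sb2 <- matrix(c(3, 3, 3, 1, 1, 1), 3, 2,
                dimnames = list(NULL, c("a", "b")))
  ri2 <- relative_importance(sb2, groups = list(g1 = "a", g2 = "b"))
  expect_equal(unname(ri2$proportion), c(1, 0))
  # exact tie goes to the first predictor in column order, counted
  sb3 <- matrix(c(2, -2), 1, 2, dimnames = list(NULL, c("a", "b")))
  ri3 <- relative_importance(sb3, groups = list(g1 = "a", g2 = "b"))
  expect_equal(unname(ri3$proportion), c(1, 0))
  expect_equal(ri3$ties, 1)
})

test_that("model comparison is deterministic and sane on pure noise", {
  b <- small_bundle(seed = 13)
  fx <- interval_fixture(b)
  cmp1 <- compare_growth_models(fx$growth, fx$coords)
  cmp2 <- compare_growth_models(fx$growth, fx$coords)
  expect_identical(as.data.frame(cmp1), as.data.frame(cmp2))
  expect_equal(sum(cmp1$akaike_weight), 1, tolerance = 1e-12)
  expect_true(all(cmp1$enp >= 2))

  # pure-noise response: GWR_C+NC cannot be near-certain
  g <- fx$growth
  set.seed(7)
  g$lambda <- rnorm(nrow(g))
  cmpn <- compare_growth_models(g, fx$coords)
  expect_lt(cmpn$akaike_weight[cmpn$model == "GWR_C+NC"], 0.99)
})

test_that("predict and plot methods work on fits", {
  set.seed(3)
  n <- 80
  d <- data.frame(x1 = rnorm(n), u = runif(n, 0, 5), v = runif(n, 0, 5))
  d$y <- 1 + d$x1 + rnorm(n, 0, 0.1)
  fit <- gwreg(y ~ x1, d, d[c("u", "v")], fraction = 0.4)
  expect_equal(predict(fit), fitted(fit))
  pr <- predict(fit, newdata = d[1:5, ], newcoords = d[1:5, c("u", "v")])
  expect_equal(pr, fitted(fit)[1:5], tolerance = 0.05)
  expect_output(print(fit), "Geographically weighted")
  expect_output(print(summary(fit)), "AICc")
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tf))
})
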