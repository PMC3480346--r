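## Geographically weighted regression: adaptive bi-square kernels, local
## weighted least squares, hat-matrix diagnostics, AICc. Authored here; lm
## and QR solves appear only as independent oracles in the test suite.

#' Bi-square kernel weight
#'
#' \eqn{w(d) = (1 - (d/b)^2)^2} for \eqn{d < b}, zero beyond the bandwidth;
#' continuous and decreasing in the distance.
#'
#' @param d Non-negative distances.
#' @param b Positive bandwidth.
#' @export
bisquare_weight <- function(d, b) {
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b <= 0) {
    stop_domain("bandwidth must be > 0")
  }
  if (any(d < 0)) stop_domain("distances must be >= 0")
  ifelse(d < b, (1 - (d / b)^2)^2, 0)
}

#' Uniform (box) kernel weight
#'
#' Weight 1 within the bandwidth (inclusive), 0 beyond. With the bandwidth
#' set by the full neighbour fraction this reduces GWR to global OLS.
#'
#' @inheritParams bisquare_weight
#' @export
uniform_weight <- function(d, b) {
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b <= 0) {
    stop_domain("bandwidth must be > 0")
  }
  if (any(d < 0)) stop_domain("distances must be >= 0")
  as.numeric(d <= b)
}

#' Adaptive kernel bandwidth at one location
#'
#' The bandwidth at location `i` is the planar Euclidean distance to its
#' k-th nearest *other* point, with `k = ceiling(fraction * (n - 1))`
#' ("fraction of the neighbouring counties", the focal county excluded). An
#' adaptive bandwidth avoids the small-sample bias a fixed radius induces
#' near coastlines and data edges.
#'
#' @param coords Two-column coordinate matrix.
#' @param i Focal location index.
#' @param fraction Neighbour fraction in (0, 1].
#' @return Positive bandwidth distance.
#' @export
adaptive_bandwidth <- function(coords, i, fraction) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) stop_domain("at least 2 locations required")
  if (!(fraction > 0 && fraction <= 1)) stop_domain("fraction must be in (0, 1]")
  d <- sqrt((coords[, 1] - coords[i, 1])^2 + (coords[, 2] - coords[i, 2])^2)
  d <- sort(d[-i])
  k <- ceiling(fraction * (n - 1))
  b <- d[k]
  if (b <= 0) stop_domain("bandwidth is zero: duplicated coordinates at location ", i)
  b
}

#' Local weighted least squares fit
#'
#' Solves \eqn{\beta = (X'WX)^{-1} X'Wy} for one location. When a focal
#' predictor row `xi` is supplied the corresponding row of the hat matrix,
#' \eqn{x_i'(X'WX)^{-1}X'W}, is returned as well. A near-singular weighted
#' cross-product (1-norm condition number above `cond_tol`) raises a
#' collinearity error of class `"gwr_collinearity_error"`.
#'
#' @param X Design matrix including the intercept column.
#' @param y Response vector.
#' @param w Non-negative weights; at least `ncol(X)` must be positive.
#' @param xi Optional focal design row (for the hat row and fitted value).
#' @param cond_tol Condition-number threshold (default 1e10).
#' @return List with `coefficients`, and when `xi` is given `fitted` and
#'   `hat_row`.
#' @export
local_fit <- function(X, y, w, xi = NULL, cond_tol = 1e10) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (sum(w > 0) < p) stop_domain("fewer positive weights than parameters")
  Xw <- X * w
  A <- crossprod(X, Xw)
  rc <- rcond(A)
  if (!is.finite(rc) || rc == 0 || 1 / rc > cond_tol) {
    cond <- if (rc > 0) 1 / rc else Inf
    stop(structure(class = c("gwr_collinearity_error", "error", "condition"),
                   list(message = sprintf(
                     "local design is collinear (condition %.3g > %.3g)",
                     cond, cond_tol), call = NULL)))
  }
  Ainv <- solve(A)
  beta <- drop(Ainv %*% crossprod(Xw, y))
  names(beta) <- colnames(X)
  out <- list(coefficients = beta)
  if (!is.null(xi)) {
    xi <- as.numeric(xi)
    out$fitted <- sum(xi * beta)
    out$hat_row <- drop((xi %*% Ainv) %*% t(Xw))
  }
  out
}

#' Standardize a regression design (z-scored predictors and response)
#'
#' z-scores every predictor and the response over the rows supplied (sample
#' SD), recording centres and scales so raw-scale coefficients are
#' recoverable: \eqn{\beta_j^{raw} = \beta_j^{std} s_y / s_{x_j}}.
#' Coefficients of a fit on this design are the standardized coefficients
#' (stdβ) whose absolute sizes are comparable across predictors.
#'
#' @param data Data frame holding response and predictors.
#' @param response Response column name (default `"lambda"`).
#' @param predictors Predictor column names (default: the eight standard
#'   predictors present in `data`).
#' @return List: `X` (with intercept), `y`, `scaling` (centres/scales),
#'   `predictors`.
#' @export
standardize_design <- function(data, response = "lambda", predictors = NULL) {
  if (is.null(predictors)) {
    predictors <- intersect(unlist(predictor_groups(), use.names = FALSE), names(data))
  }
  if (nrow(data) < 2) stop_domain("need at least 2 rows to standardize")
  Xr <- as.matrix(data[predictors])
  sds <- col_sds(Xr)
  bad <- predictors[!is.finite(sds) | sds == 0]
  if (length(bad)) {
    stop_domain("zero-variance predictor(s): ", paste(bad, collapse = ", "))
  }
  y <- data[[response]]
  sy <- stats::sd(y)
  if (sy == 0) stop_domain("zero-variance response")
  Xs <- scale(Xr, center = TRUE, scale = sds)
  X <- cbind(`(Intercept)` = 1, Xs)
  list(X = X, y = (y - mean(y)) / sy,
       scaling = list(x_center = colMeans(Xr), x_scale = sds,
                      y_center = mean(y), y_scale = sy),
       predictors = predictors)
}

#' Convert standardized coefficients back to the raw scale
#'
#' @param beta Coefficient vector or matrix (columns named `(Intercept)`
#'   plus predictors) from a standardized fit.
#' @param scaling The `scaling` element of [standardize_design()].
#' @export
unstandardize_coef <- function(beta, scaling) {
  one <- is.null(dim(beta))
  B <- if (one) matrix(beta, 1, dimnames = list(NULL, names(beta))) else beta
  pred <- setdiff(colnames(B), "(Intercept)")
  out <- B
  for (j in pred) {
    out[, j] <- B[, j] * scaling$y_scale / scaling$x_scale[j]
  }
  out[, "(Intercept)"] <- scaling$y_center + B[, "(Intercept)"] * scaling$y_scale -
    as.vector(out[, pred, drop = FALSE] %*% scaling$x_center[pred])
  if (one) out[1, ] else out
}

#' Effective number of parameters of a linear smoother
#'
#' The trace of the hat matrix; for GWR, the sum of the per-location hat
#' diagonal. Equals the parameter count for global OLS and grows towards
#' `n` as bandwidths shrink.
#'
#' @param hat_diag Hat-matrix diagonal.
#' @export
effective_parameters <- function(hat_diag) sum(hat_diag)

#' Small-sample corrected AICc for a GWR-type smoother
#'
#' The Fotheringham/Brunsdon/Charlton form with \eqn{\hat\sigma^2 = RSS/n}:
#' \deqn{AICc = n\log(RSS/n) + n\log(2\pi) + n\frac{n + tr(S)}{n - 2 - tr(S)}.}
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of observations.
#' @param enp Effective number of parameters (trace of the hat matrix);
#'   requires `n > enp + 2`.
#' @export
gwr_aicc <- function(rss, n, enp) {
  if (rss <= 0) stop_domain("rss must be > 0")
  if (n <= enp + 2) stop_domain("AICc undefined: n must exceed enp + 2")
  n * log(rss / n) + n * log(2 * pi) + n * (n + enp) / (n - 2 - enp)
}

#' Akaike weights from AICc values
#'
#' \eqn{w_m = \exp(-\Delta_m/2) / \sum_k \exp(-\Delta_k/2)} with
#' \eqn{\Delta_m = AICc_m - \min AICc}; sums to 1.
#'
#' @param aicc Vector of AICc values (length >= 2).
#' @export
akaike_weights <- function(aicc) {
  if (length(aicc) < 2) stop_domain("need at least 2 models")
  d <- aicc - min(aicc)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Geographically weighted regression
#'
#' Fits one weighted least-squares regression per location: coefficients at
#' location \eqn{i} are \eqn{\beta(i) = (X'W_iX)^{-1}X'W_iy} where
#' \eqn{W_i} holds kernel weights decaying with planar distance from
#' location \eqn{i}. The default kernel is adaptive bi-square: at each
#' location the bandwidth is the distance to the `fraction` share of
#' neighbouring locations ([adaptive_bandwidth()]), so sparse regions use
#' wider windows. If any location's local design is collinear (condition
#' number above `cond_tol`) the whole fit is retried at the next fallback
#' fraction, mirroring the practice of widening bandwidths under high
#' spatial collinearity among predictors.
#'
#' @param formula Model formula, e.g. `lambda ~ annual_temp + income_z`.
#' @param data Data frame holding the variables.
#' @param coords Two-column matrix (or data frame) of location coordinates,
#'   one row per row of `data`.
#' @param fraction Adaptive neighbour fraction in (0, 1] (default 0.3).
#' @param kernel `"bisquare"` (default) or `"uniform"`.
#' @param fallback Increasing fallback fractions tried on collinearity
#'   failure (default `c(0.45, 0.5)`).
#' @param standardize `"none"` (raw variables), `"x"` (z-score predictors
#'   only) or `"xy"` (z-score predictors and response; coefficients are then
#'   stdβ). Default `"none"`.
#' @param cond_tol Local condition-number threshold (default 1e10).
#' @return Object of class `"gwreg"` with per-location `coefficients`
#'   (n x p matrix), `fitted.values`, `residuals`, `hat_diag`, `bandwidth`,
#'   and global `rss`, `enp`, `aicc`, plus bookkeeping fields.
#' @examples
#' d <- data.frame(x1 = rnorm(50), u = runif(50), v = runif(50))
#' d$y <- 1 + 2 * d$x1 + rnorm(50, 0, 0.1)
#' fit <- gwreg(y ~ x1, d, coords = d[c("u", "v")], fraction = 0.5)
#' summary(fit)
#' @export
gwreg <- function(formula, data, coords, fraction = 0.3,
                  kernel = c("bisquare", "uniform"),
                  fallback = c(0.45, 0.5), standardize = c("none", "x", "xy"),
                  cond_tol = 1e10) {
  kernel <- match.arg(kernel)
  standardize <- match.arg(standardize)
  cl <- match.call()
  coords <- as.matrix(coords)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- nrow(X)
  p <- ncol(X)
  if (nrow(coords) != n || ncol(coords) != 2) {
    stop_domain("coords must be a 2-column matrix aligned with data rows")
  }
  scaling <- NULL
  if (standardize != "none") {
    pred <- setdiff(colnames(X), "(Intercept)")
    sds <- col_sds(X[, pred, drop = FALSE])
    if (any(sds == 0)) {
      stop_domain("zero-variance predictor(s): ",
                  paste(pred[sds == 0], collapse = ", "))
    }
    ctr <- colMeans(X[, pred, drop = FALSE])
    X[, pred] <- scale(X[, pred, drop = FALSE], center = ctr, scale = sds)
    sy <- 1; cy <- 0
    if (standardize == "xy") {
      sy <- stats::sd(y); cy <- mean(y)
      if (sy == 0) stop_domain("zero-variance response")
      y <- (y - cy) / sy
    }
    scaling <- list(x_center = ctr, x_scale = sds, y_center = cy, y_scale = sy)
  }

  kfun <- if (kernel == "bisquare") bisquare_weight else uniform_weight
  D <- as.matrix(stats::dist(coords))

  fractions <- c(fraction, fallback[fallback > fraction])
  fit_try <- function(frac) {
    k <- ceiling(frac * (n - 1))
    coefs <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(X)))
    fitted <- hat <- bw <- numeric(n)
    for (i in seq_len(n)) {
      di <- D[, i]
      b <- sort(di[-i])[k]
      if (b <= 0) stop_domain("duplicated coordinates at location ", i)
      w <- kfun(di, b)
      idx <- which(w > 0)
      lf <- tryCatch(
        local_fit(X[idx, , drop = FALSE], y[idx], w[idx],
                  xi = X[i, ], cond_tol = cond_tol),
        gwr_collinearity_error = function(e) {
          stop(structure(class = c("gwr_collinearity_error", "error", "condition"),
                         list(message = sprintf("location %d: %s", i,
                                                conditionMessage(e)),
                              call = NULL)))
        })
      coefs[i, ] <- lf$coefficients
      fitted[i] <- lf$fitted
      hat[i] <- lf$hat_row[match(i, idx)]
      bw[i] <- b
    }
    list(coefs = coefs, fitted = fitted, hat = hat, bw = bw, fraction = frac)
  }

  res <- NULL
  for (frac in fractions) {
    res <- tryCatch(fit_try(frac), gwr_collinearity_error = function(e) {
      message(sprintf("gwreg: fraction %.2f failed (%s); trying fallback",
                      frac, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) break
  }
  if (is.null(res)) {
    stop_domain("GWR failed at all fallback fractions (",
                paste(fractions, collapse = ", "), ")")
  }

  residuals <- y - res$fitted
  rss <- sum(residuals^2)
  enp <- effective_parameters(res$hat)
  aicc <- if (n > enp + 2 && rss > 0) gwr_aicc(rss, n, enp) else NA_real_

  structure(list(
    call = cl, formula = formula, kernel = kernel,
    fraction = fraction, fraction_used = res$fraction,
    coefficients = res$coefs, fitted.values = res$fitted,
    residuals = residuals, hat_diag = res$hat, bandwidth = res$bw,
    rss = rss, enp = enp, aicc = aicc, n = n, p = p,
    y = y, X = X, coords = coords, standardize = standardize,
    scaling = scaling, cond_tol = cond_tol,
    aicc_variant = "n*log(rss/n) + n*log(2*pi) + n*(n+enp)/(n-2-enp)"
  ), class = "gwreg")
}

#' @export
print.gwreg <- function(x, digits = 4, ...) {
  cat("Geographically weighted regression\n")
  cat("Call: "); print(x$call)
  cat(sprintf("n = %d locations, %s kernel, adaptive fraction %.2f%s\n",
              x$n, x$kernel, x$fraction_used,
              if (x$fraction_used != x$fraction) " (fallback)" else ""))
  cat(sprintf("Effective parameters %.2f, RSS %.6g, AICc %.2f\n",
              x$enp, x$rss, x$aicc))
  cat("Coefficient summary (across locations):\n")
  print(round(t(apply(x$coefficients, 2, stats::quantile)), digits))
  invisible(x)
}

#' @export
coef.gwreg <- function(object, ...) object$coefficients

#' @export
fitted.gwreg <- function(object, ...) object$fitted.values

#' @export
residuals.gwreg <- function(object, ...) object$residuals

#' @export
summary.gwreg <- function(object, ...) {
  q <- t(apply(object$coefficients, 2, stats::quantile))
  colnames(q) <- c("Min", "Q1", "Median", "Q3", "Max")
  structure(list(call = object$call, n = object$n, kernel = object$kernel,
                 fraction_used = object$fraction_used, coef_quartiles = q,
                 enp = object$enp, rss = object$rss, aicc = object$aicc,
                 sigma2 = object$rss / object$n,
                 r2 = 1 - object$rss / sum((object$y - mean(object$y))^2),
                 bandwidth_range = range(object$bandwidth)),
            class = "summary.gwreg")
}

#' @export
print.summary.gwreg <- function(x, digits = 4, ...) {
  cat("Geographically weighted regression\n")
  cat("Call: "); print(x$call)
  cat(sprintf("n = %d, %s kernel, fraction %.2f, bandwidth %.3g-%.3g\n",
              x$n, x$kernel, x$fraction_used,
              x$bandwidth_range[1], x$bandwidth_range[2]))
  cat("Per-location coefficients:\n")
  print(round(x$coef_quartiles, digits))
  cat(sprintf("enp %.2f, RSS %.6g, sigma2 %.6g, R2 %.4f, AICc %.2f\n",
              x$enp, x$rss, x$sigma2, x$r2, x$aicc))
  invisible(x)
}

#' Predict from a GWR fit
#'
#' Without new data, returns the fitted values. With `newdata` and
#' `newcoords`, fits a local model at each new location from the training
#' data (bandwidth = distance to the `fraction_used` share of training
#' points) and evaluates it at the new predictor row.
#'
#' @param object A `"gwreg"` fit.
#' @param newdata Data frame of new predictor values.
#' @param newcoords Matching 2-column coordinates.
#' @param ... Unused.
#' @export
predict.gwreg <- function(object, newdata = NULL, newcoords = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (is.null(newcoords)) stop_domain("newcoords required with newdata")
  newcoords <- as.matrix(newcoords)
  tt <- stats::delete.response(stats::terms(object$formula))
  Xn <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  if (object$standardize != "none") {
    pred <- names(object$scaling$x_scale)
    Xn[, pred] <- scale(Xn[, pred, drop = FALSE],
                        center = object$scaling$x_center,
                        scale = object$scaling$x_scale)
  }
  kfun <- if (object$kernel == "bisquare") bisquare_weight else uniform_weight
  k <- ceiling(object$fraction_used * (object$n - 1))
  out <- numeric(nrow(Xn))
  for (j in seq_len(nrow(Xn))) {
    d <- sqrt((object$coords[, 1] - newcoords[j, 1])^2 +
                (object$coords[, 2] - newcoords[j, 2])^2)
    b <- sort(d)[min(k, length(d))]
    if (b <= 0) b <- min(d[d > 0])
    w <- kfun(d, b)
    lf <- local_fit(object$X[w > 0, , drop = FALSE], object$y[w > 0], w[w > 0],
                    cond_tol = object$cond_tol)
    out[j] <- sum(Xn[j, ] * lf$coefficients)
  }
  if (object$standardize == "xy") {
    out <- out * object$scaling$y_scale + object$scaling$y_center
  }
  out
}

#' Map a coefficient surface from a GWR fit
#'
#' Plots locations coloured by the local coefficient of one predictor, a
#' quick numeric rendering of spatial non-stationarity.
#'
#' @param x A `"gwreg"` fit.
#' @param which Coefficient name or index (default the first non-intercept).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gwreg <- function(x, which = NULL, ...) {
  cn <- colnames(x$coefficients)
  if (is.null(which)) which <- if (length(cn) > 1) cn[2] else cn[1]
  b <- x$coefficients[, which]
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  col <- pal[cut(b, 64, labels = FALSE)]
  graphics::plot(x$coords[, 1], x$coords[, 2], col = col, pch = 16,
                 xlab = "x", ylab = "y",
                 main = paste("Local coefficient:", which), ...)
  invisible(x)
}
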