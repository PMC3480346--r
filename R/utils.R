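#' @keywords internal
"_PACKAGE"

## Internal argument checks -------------------------------------------------

stop_domain <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_domain(name, " must be numeric and non-missing")
  }
  if (positive && any(x <= 0)) stop_domain(name, " must be > 0")
  if (nonneg && any(x < 0)) stop_domain(name, " must be >= 0")
  invisible(x)
}

## Sample standard deviation of the columns of a matrix, vectorised.
col_sds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt(colSums((m - rep(mu, each = n))^2) / (n - 1))
}
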