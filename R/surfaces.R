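## Coefficient-surface specifications for the synthetic generator: each
## predictor's local effect beta_j(x, y) is a constant, a linear gradient,
## or a Gaussian bump over the lattice.

#' Coefficient surface constructors
#'
#' Build the spatially varying coefficient surfaces used by the synthetic
#' generator's growth model.
#'
#' * `surface_constant(value)`: \eqn{\beta(x,y) = value}.
#' * `surface_gradient(intercept, dx, dy, center)`: \eqn{\beta(x,y) =
#'   intercept + dx (x - c_x) + dy (y - c_y)}; centring keeps `intercept`
#'   the value at `center`.
#' * `surface_bump(height, cx, cy, sd, base)`: Gaussian bump
#'   \eqn{base + height \exp(-((x-c_x)^2+(y-c_y)^2) / (2 sd^2))}.
#'
#' @param value,intercept,base Constant levels.
#' @param dx,dy Gradient per lattice unit.
#' @param center Gradient centre `c(x, y)`.
#' @param height,cx,cy,sd Bump height, centre and width.
#' @return A `"coef_surface"` specification.
#' @export
surface_constant <- function(value) {
  structure(list(kind = "constant", value = value), class = "coef_surface")
}

#' @rdname surface_constant
#' @export
surface_gradient <- function(intercept = 0, dx = 0, dy = 0, center = c(0, 0)) {
  structure(list(kind = "gradient", intercept = intercept, dx = dx, dy = dy,
                 center = center), class = "coef_surface")
}

#' @rdname surface_constant
#' @export
surface_bump <- function(height, cx, cy, sd, base = 0) {
  if (sd <= 0) stop_domain("bump sd must be > 0")
  structure(list(kind = "bump", height = height, cx = cx, cy = cy, sd = sd,
                 base = base), class = "coef_surface")
}

#' Evaluate a coefficient surface at coordinates
#'
#' @param spec A `"coef_surface"`.
#' @param x,y Coordinates.
#' @export
eval_surface <- function(spec, x, y) {
  if (!inherits(spec, "coef_surface")) stop_domain("not a coef_surface")
  switch(spec$kind,
    constant = rep(spec$value, length(x)),
    gradient = spec$intercept + spec$dx * (x - spec$center[1]) +
      spec$dy * (y - spec$center[2]),
    bump = spec$base + spec$height *
      exp(-((x - spec$cx)^2 + (y - spec$cy)^2) / (2 * spec$sd^2)),
    stop_domain("unknown surface kind: ", spec$kind)
  )
}
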