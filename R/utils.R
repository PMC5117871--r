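# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Gaussian smoothing of a 1D signal sampled on a uniform grid.
# sigma is in grid units of `dx` (pass sigma_um / dx_um). Reflective padding
# so profile ends are not dragged toward zero.
#' @noRd
gauss_smooth1d <- function(y, sigma) {
  if (sigma <= 0) return(y)
  n <- length(y)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  ypad <- c(y[pmin(half:1, n)], y, y[pmax(n - (1:half) + 1L, 1L)])
  out <- stats::filter(ypad, k, sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}

# Centered first derivative on a uniform grid (one-sided at the ends).
#' @noRd
grad1d <- function(y, dx) {
  n <- length(y)
  if (n < 2L) stop("need at least two points to differentiate")
  g <- numeric(n)
  g[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / (2 * dx)
  g[1L] <- (y[2L] - y[1L]) / dx
  g[n] <- (y[n] - y[n - 1L]) / dx
  g
}

# Linear interpolation with rule = 2 (clamped ends); NA-safe for aligned grids.
#' @noRd
interp_onto <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2)$y
}

# Check for a strictly increasing numeric grid.
#' @noRd
assert_grid <- function(x, name = "x") {
  if (!is.numeric(x) || length(x) < 2L || any(!is.finite(x)) || any(diff(x) <= 0))
    stop(sprintf("'%s' must be a strictly increasing numeric grid", name))
  invisible(x)
}

# Uniform grid spacing (errors if grid is visibly non-uniform).
#' @noRd
grid_dx <- function(x, tol = 1e-6) {
  d <- diff(x)
  if ((max(d) - min(d)) > tol * mean(d))
    stop("grid must be uniformly spaced")
  mean(d)
}
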