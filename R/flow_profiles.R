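#' Specify an analytic AP-axis flow profile
#'
#' Describes an anterior–posterior (AP) cortical flow velocity profile v(x)
#' used to drive synthetic data generation. Positions are in micrometres with
#' the embryo centre at 0 (anterior negative); velocities are in micrometres
#' per minute, negative values meaning anterior-directed flow.
#'
#' Shapes:
#' \describe{
#'   \item{`gaussian_bump`}{`v(x) = peak_velocity * exp(-(x - center)^2 / (2 width^2))`.
#'     With a negative peak velocity this produces a compression peak
#'     (`-dv/dx > 0`) at `center - width`.}
#'   \item{`tanh_front`}{`v(x) = peak_velocity/2 * (1 + tanh((x - center)/width))`,
#'     a flow front ramping from 0 to `peak_velocity` with its compression
#'     peak `-peak_velocity/(2*width)` at `center`.}
#'   \item{`linear`}{`v(x) = peak_velocity * (x - center) / width`, constant
#'     velocity gradient `peak_velocity / width`.}
#' }
#'
#' @param shape one of `"gaussian_bump"`, `"tanh_front"`, `"linear"`.
#' @param peak_velocity peak flow speed, micrometres/min (sign carries direction).
#' @param center profile centre, micrometres.
#' @param width profile width scale, micrometres; must be positive.
#' @param grid strictly increasing vector of x positions (micrometres).
#' @return an object of class `flow_profile_spec`.
#' @seealso [generate_flow_profile()]
#' @export
flow_profile_spec <- function(shape = c("gaussian_bump", "tanh_front", "linear"),
                              peak_velocity, center = 0, width,
                              grid = seq(-15, 15, by = 0.5)) {
  shape <- match.arg(shape)
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("'width' must be a positive scalar")
  assert_grid(grid, "grid")
  structure(list(shape = shape, peak_velocity = peak_velocity,
                 center = center, width = width, grid = grid),
            class = "flow_profile_spec")
}

#' Evaluate a flow profile and its analytic derivative
#'
#' @param spec a [flow_profile_spec()].
#' @return a data frame of class `velocity_profile` with columns `x`
#'   (micrometres), `v` (micrometres/min) and `dvdx` (1/min, the analytic
#'   velocity gradient; the compression rate is `-dvdx`).
#' @examples
#' vp <- generate_flow_profile(flow_profile_spec("gaussian_bump",
#'   peak_velocity = -5, center = 0, width = 5))
#' min(vp$v)  # -5 at the centre
#' @export
generate_flow_profile <- function(spec) {
  stopifnot(inherits(spec, "flow_profile_spec"))
  x <- spec$grid
  u <- (x - spec$center) / spec$width
  pv <- spec$peak_velocity
  w <- spec$width
  if (spec$shape == "gaussian_bump") {
    v <- pv * exp(-u^2 / 2)
    dvdx <- -pv * u / w * exp(-u^2 / 2)
  } else if (spec$shape == "tanh_front") {
    v <- pv / 2 * (1 + tanh(u))
    dvdx <- pv / (2 * w) * (1 / cosh(u))^2
  } else {
    v <- pv * u
    dvdx <- rep(pv / w, length(x))
  }
  structure(data.frame(x = x, v = v, dvdx = dvdx),
            class = c("velocity_profile", "data.frame"))
}
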