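# Compression rates, flow-onset timing, stationary-phase selection and
# AP intensity profiles.

#' Compression rate from a velocity profile
#'
#' Gaussian-smooths the velocity profile and returns the negative centred
#' spatial gradient, `-dv/dx` (1/min; positive values mean the gel is being
#' compressed). Defined on the interior of the velocity grid.
#'
#' @param profile data frame with columns `x` (micrometres, uniform grid)
#'   and `v` (micrometres/min), e.g. from [velocity_profile()].
#' @param smooth_sigma Gaussian smoothing length, micrometres (default 2;
#'   0 disables smoothing).
#' @return data frame of class `compression_profile` with columns `x` and
#'   `rate` on the interior grid points.
#' @export
compression_rate <- function(profile, smooth_sigma = 2) {
  stopifnot(all(c("x", "v") %in% names(profile)))
  x <- profile$x; v <- profile$v
  if (length(x) < 5L) stop("velocity grid too short (need >= 5 points)")
  assert_grid(x)
  dx <- grid_dx(x)
  vs <- gauss_smooth1d(v, smooth_sigma / dx)
  n <- length(x)
  i <- 2:(n - 1L)
  rate <- -(vs[i + 1L] - vs[i - 1L]) / (2 * dx)
  out <- data.frame(x = x[i], rate = rate)
  class(out) <- c("compression_profile", "data.frame")
  out
}

#' Fit the flow onset time with an error-function rise
#'
#' Least-squares fit of `v(t) = a + b * erf((t - t0) / s)` to a velocity
#' time series at fixed position, used to define the reference time (flow
#' onset) of each embryo.
#'
#' @param t time points, min (at least 8, spanning the rise).
#' @param v velocity values, micrometres/min.
#' @return list of class `onset_fit` with `t0` (min), coefficients `a`,
#'   `b`, `s`, and the `nls` fit object.
#' @export
fit_onset_time <- function(t, v) {
  stopifnot(length(t) == length(v))
  if (length(t) < 8L) stop("need at least 8 time points spanning the rise")
  if (stats::sd(v) < 1e-12 * max(1, abs(mean(v))))
    stop("degenerate rise: velocity series is constant")
  a0 <- mean(range(v))
  b0 <- diff(range(v)) / 2 * sign(stats::cor(t, v))
  t00 <- stats::approx(v, t, xout = a0, ties = mean)$y
  if (!is.finite(t00)) t00 <- stats::median(t)
  s0 <- diff(range(t)) / 4
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ a + b * erf((t - t0) / s),
                      start = list(a = a0, b = b0, t0 = t00, s = s0),
                      data = data.frame(t = t, v = v),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("onset fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  structure(list(t0 = unname(cf["t0"]), a = unname(cf["a"]),
                 b = unname(cf["b"]), s = abs(unname(cf["s"])), fit = fit),
            class = "onset_fit")
}

#' Select the stationary flow phase
#'
#' Finds the longest contiguous time window (of at least `min_duration`)
#' in which every supplied series stays within `rel_tol` (relative to the
#' window median of that series) of its window median — the period during
#' which flow and compression are treated as stationary.
#'
#' @param t time points, min (aligned to flow onset).
#' @param series a numeric vector or list of numeric vectors (e.g. central
#'   mean velocity and central compression rate vs time).
#' @param rel_tol relative tolerance (default 0.1).
#' @param min_duration minimum window length, min (default 1).
#' @return list of class `stationary_window` with `t_start`, `t_end` (min)
#'   and the index range `i_start`, `i_end`.
#' @export
detect_stationary_window <- function(t, series, rel_tol = 0.1,
                                     min_duration = 1) {
  if (is.numeric(series)) series <- list(series)
  stopifnot(all(vapply(series, length, 1L) == length(t)))
  n <- length(t)
  best <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in seq(n, i + 1L)) {
      if (t[j] - t[i] < min_duration) break
      if (!is.null(best) && (t[j] - t[i]) <= (best$t_end - best$t_start)) break
      ok <- all(vapply(series, function(s) {
        w <- s[i:j]
        md <- stats::median(w)
        all(abs(w - md) <= rel_tol * abs(md))
      }, logical(1L)))
      if (ok) {
        best <- list(t_start = t[i], t_end = t[j], i_start = i, i_end = j)
        break
      }
    }
  }
  if (is.null(best))
    stop("no stationary window of at least ", min_duration,
         " min at rel_tol = ", rel_tol)
  class(best) <- "stationary_window"
  best
}

#' AP-axis intensity profile of an image
#'
#' Band-mean intensity per x position, optionally subtracting the median of
#' the image edge (outermost rows/columns) as background.
#'
#' @param image intensity matrix (rows = y, cols = x).
#' @param y_band optional y range (micrometres, image centre at 0) to
#'   average over.
#' @param pixel_size micrometres per px.
#' @param background `"none"` (default) or `"edge"` (subtract the median
#'   over a 3-px image border).
#' @return data frame of class `intensity_profile` with columns `x`
#'   (micrometres) and `intensity`.
#' @export
intensity_profile <- function(image, y_band = NULL, pixel_size = 0.1,
                              background = c("none", "edge")) {
  stopifnot(is.matrix(image))
  background <- match.arg(background)
  H <- nrow(image); W <- ncol(image)
  y_um <- (seq_len(H) - (H + 1) / 2) * pixel_size
  rows <- if (is.null(y_band)) seq_len(H)
          else which(y_um >= y_band[1L] & y_um <= y_band[2L])
  if (length(rows) == 0L) stop("empty y band")
  bg <- 0
  if (background == "edge") {
    border <- rbind(image[1:3, , drop = FALSE],
                    image[(H - 2):H, , drop = FALSE])
    bg <- stats::median(c(border, image[, 1:3], image[, (W - 2):W]))
  }
  out <- data.frame(x = (seq_len(W) - (W + 1) / 2) * pixel_size,
                    intensity = colMeans(image[rows, , drop = FALSE]) - bg)
  class(out) <- c("intensity_profile", "data.frame")
  out
}
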