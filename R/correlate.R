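# Spatial/spatiotemporal cross-correlation between AP profiles, Gaussian
# peak localisation, distance-to-delay conversion, and radial
# autocorrelation for foci sizing.

#' Spatial cross-correlation of two AP profiles
#'
#' Mean-subtracted, sd-normalised cross-correlation between two profiles
#' (or kymographs, one column per time point) restricted to a central
#' region, averaged over the supplied time points. Lags are limited to
#' half the region width. The correlation at lag d compares `f(x)` with
#' `g(x + d)`, so a positive peak lag means features of `g` lie at larger
#' x (posterior) of the corresponding features of `f`.
#'
#' @param f,g numeric vectors on the common grid `x`, or matrices with one
#'   column per time point.
#' @param x common position grid, micrometres (uniform).
#' @param region x range used, micrometres; default the central 30
#'   micrometres `c(-15, 15)`.
#' @param times optional column indices (time points of the stationary
#'   window) when `f`, `g` are kymographs.
#' @return data frame of class `correlation_curve` with columns `lag`
#'   (micrometres) and `C`; attribute `region`.
#' @export
cross_correlate <- function(f, g, x, region = c(-15, 15), times = NULL) {
  if (is.matrix(f) || is.matrix(g)) {
    f <- as.matrix(f); g <- as.matrix(g)
    stopifnot(nrow(f) == length(x), identical(dim(f), dim(g)))
    if (is.null(times)) times <- seq_len(ncol(f))
  } else {
    stopifnot(length(f) == length(x), length(g) == length(x))
    f <- matrix(f, ncol = 1L); g <- matrix(g, ncol = 1L)
    times <- 1L
  }
  assert_grid(x)
  dx <- grid_dx(x)
  keep <- which(x >= region[1L] & x <= region[2L])
  if (length(keep) < 5L) stop("region contains too few grid points")
  max_lag <- floor(length(keep) / 2)
  lags <- -max_lag:max_lag
  curves <- vapply(times, function(tt) {
    fv <- f[keep, tt]; gv <- g[keep, tt]
    if (stats::sd(fv) < 1e-12 || stats::sd(gv) < 1e-12)
      stop("correlation undefined: constant field within the region")
    vapply(lags, function(d) {
      # Pearson correlation on the overlapping segment, so C in [-1, 1]
      if (d >= 0) {
        i <- seq_len(length(keep) - d)
        a <- fv[i]; b <- gv[i + d]
      } else {
        i <- seq_len(length(keep) + d)
        a <- fv[i - d]; b <- gv[i]
      }
      if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
      stats::cor(a, b)
    }, numeric(1L))
  }, numeric(length(lags)))
  out <- data.frame(lag = lags * dx, C = rowMeans(curves))
  attr(out, "region") <- region
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Locate a correlation peak by Gaussian fitting
#'
#' Least-squares fit of a Gaussian (plus offset) to the correlation curve
#' within `support` micrometres of its discrete maximum; the fitted centre
#' is the peak offset.
#'
#' @param curve a `correlation_curve` (or data frame with `lag`, `C`).
#' @param support half-width of the fit support, micrometres (default 5).
#' @return list of class `peak_offset` with `offset` (micrometres), `se`
#'   (standard error of the centre) and the `nls` fit.
#' @export
gaussian_peak_offset <- function(curve, support = 5) {
  stopifnot(all(c("lag", "C") %in% names(curve)))
  i0 <- which.max(curve$C)
  if (i0 == 1L || i0 == nrow(curve))
    stop("correlation maximum lies at a lag boundary; peak not localised")
  sel <- abs(curve$lag - curve$lag[i0]) <= support
  d <- curve[sel, ]
  if (nrow(d) < 5L) stop("too few points around the peak for a Gaussian fit")
  resid_fun <- function(p)
    d$C - (p[4L] + p[1L] * exp(-(d$lag - p[2L])^2 / (2 * p[3L]^2)))
  # sig start from the observed half-maximum half-width
  half <- min(abs(d$lag[d$C <= (max(d$C) + min(d$C)) / 2] - curve$lag[i0]),
              support)
  start <- c(max(d$C) - min(d$C), curve$lag[i0],
             max(half / 1.18, 0.5), min(d$C))
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, maxfev = 5000))
  if (fit$info < 1 || fit$info > 4)
    stop("Gaussian peak fit failed: ", fit$message)
  # linearised standard error of the centre: cov = 2 s^2 H^-1
  se <- NA_real_
  dof <- nrow(d) - 4L
  if (dof > 0) {
    s2 <- fit$deviance / dof
    cov <- tryCatch(2 * s2 * solve(fit$hessian), error = function(e) NULL)
    if (!is.null(cov) && cov[2L, 2L] >= 0) se <- sqrt(cov[2L, 2L])
  }
  structure(list(offset = fit$par[2L], se = se, fit = fit),
            class = "peak_offset")
}

#' Convert a stationary peak offset to a temporal delay
#'
#' In a stationary flow, a spatial offset between the peaks of two
#' co-moving fields corresponds to a temporal delay `dt = dx / |v|` in the
#' frame co-moving with the flow, with `v` the mean central flow speed.
#' The velocity uncertainty is propagated to first order.
#'
#' @param offset peak offset, micrometres, measured positive in the
#'   downstream (along-flow) direction; for anterior-directed flow a raw
#'   [cross_correlate()] lag converts as `lag * sign(v_mean)`.
#' @param v_mean mean central flow velocity, micrometres/min (nonzero; the
#'   magnitude is used).
#' @param v_sd standard deviation of the velocity (optional).
#' @param offset_se standard error of the offset (optional).
#' @return list of class `delay_result` with `delay` (min; positive when
#'   the second field lags, i.e. lies downstream — anterior-ward — of the
#'   first for anterior-directed flow), `delay_sd`, `offset`, `v_mean`.
#' @examples
#' # the cytokinesis compression-to-alignment delay:
#' offset_to_delay(1.60, v_mean = 4.01)$delay  # 0.40 min
#' @export
offset_to_delay <- function(offset, v_mean, v_sd = NA_real_,
                            offset_se = NA_real_) {
  if (abs(v_mean) < 1e-12)
    stop("zero mean velocity: no co-moving frame")
  delay <- offset / abs(v_mean)
  rel2 <- 0
  if (is.finite(v_sd)) rel2 <- rel2 + (v_sd / v_mean)^2
  if (is.finite(offset_se) && abs(offset) > 1e-12)
    rel2 <- rel2 + (offset_se / offset)^2
  structure(list(delay = delay,
                 delay_sd = if (rel2 > 0) abs(delay) * sqrt(rel2) else NA_real_,
                 offset = offset, v_mean = v_mean),
            class = "delay_result")
}

#' Radial autocorrelation and characteristic feature size
#'
#' Azimuthally averaged, normalised spatial autocorrelation of an image
#' (FFT-based, mean-subtracted). The characteristic size is the radius at
#' which the correlation first falls below 1/e (linearly interpolated);
#' for an isolated Gaussian focus of sd sigma px this is 2*sigma.
#'
#' @param image non-constant intensity matrix.
#' @param max_radius largest radius evaluated, px (default a quarter of the
#'   smaller image side).
#' @return list of class `radial_acf` with `r` (px), `C`, and `size` (px).
#' @export
radial_autocorrelation <- function(image, max_radius = NULL) {
  stopifnot(is.matrix(image))
  if (stats::sd(image) < 1e-14) stop("constant image: autocorrelation undefined")
  H <- nrow(image); W <- ncol(image)
  if (is.null(max_radius)) max_radius <- floor(min(H, W) / 4)
  M1 <- 2L * H; M2 <- 2L * W
  A <- matrix(0, M1, M2)
  A[1:H, 1:W] <- image - mean(image)
  F <- stats::fft(A)
  ac <- Re(stats::fft(F * Conj(F), inverse = TRUE)) / (M1 * M2)
  # overlap normalisation, then C(0) = 1
  sh1 <- c(0:(H - 1L), -(H:1L))[c(1:H, (M1 - H + 1L):M1)]
  dy <- c(0:(M1 / 2 - 1L), -(M1 / 2):-1L)
  dxs <- c(0:(M2 / 2 - 1L), -(M2 / 2):-1L)
  ov <- outer(pmax(H - abs(dy), 1), pmax(W - abs(dxs), 1))
  ac <- ac / ov
  ac <- ac / ac[1L, 1L]
  r <- sqrt(outer(dy^2, dxs^2, `+`))
  rb <- round(r)
  sel <- rb <= max_radius
  Cr <- as.numeric(tapply(ac[sel], rb[sel], mean))
  rr <- as.numeric(names(tapply(ac[sel], rb[sel], mean)))
  o <- order(rr); rr <- rr[o]; Cr <- Cr[o]
  size <- NA_real_
  below <- which(Cr < exp(-1))
  if (length(below) > 0L) {
    i <- below[1L]
    if (i == 1L) size <- rr[1L]
    else size <- rr[i - 1L] + (exp(-1) - Cr[i - 1L]) /
        (Cr[i] - Cr[i - 1L]) * (rr[i] - rr[i - 1L])
  }
  structure(list(r = rr, C = Cr, size = size), class = "radial_acf")
}
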