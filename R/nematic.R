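# Nematic order quantification from windowed Fourier orientation spectra.
#
# The power spectrum of a small image window concentrates along the
# direction perpendicular to the dominant filament orientation; binning the
# annulus-restricted power by wavevector angle (rotated by pi/2) yields an
# orientation distribution p(theta) on [0, pi), from which the nematic
# tensor components follow as its second circular moments.

#' Orientation distribution of an image window from its Fourier spectrum
#'
#' Computes the angular distribution of filament orientations within a
#' square window: the window is mean-subtracted, tapered with a 2D Hann
#' window, Fourier transformed, and the spectral power inside a wavenumber
#' annulus (spatial periods `period_range` px, excluding DC and
#' near-Nyquist) is binned by wavevector angle rotated by pi/2 so that
#' angles refer to real-space filament orientation measured from the x
#' axis. The azimuthal mean of the power at each radius (the isotropic
#' noise floor) is subtracted, with negative residuals clipped, before
#' binning.
#'
#' @param window square intensity matrix, at least 16 px on a side.
#' @param n_bins number of angular bins on `[0, pi)` (default 180, 1 degree).
#' @param period_range spatial periods (px) defining the annulus, default
#'   `c(4, 16)`.
#' @param background_subtract subtract the per-radius azimuthal mean power
#'   before binning (default TRUE).
#' @return list of class `orientation_spectrum` with `theta` (bin centres,
#'   rad) and `p` (density, integrates to 1). A constant window returns a
#'   flat density with attribute `undefined = TRUE`.
#' @export
window_orientation_spectrum <- function(window, n_bins = 180,
                                        period_range = c(4, 16),
                                        background_subtract = TRUE) {
  stopifnot(is.matrix(window))
  N <- nrow(window)
  if (N < 16L || ncol(window) != N)
    stop("window must be square and at least 16 px")
  dtheta <- pi / n_bins
  theta_centers <- (seq_len(n_bins) - 0.5) * dtheta
  flat <- structure(list(theta = theta_centers, p = rep(1 / pi, n_bins)),
                    class = "orientation_spectrum")
  w <- window - mean(window)
  if (max(abs(w)) < 1e-12) {
    attr(flat, "undefined") <- TRUE
    return(flat)
  }
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(N) - 1) / (N - 1)))
  P <- Mod(stats::fft(w * outer(hann, hann)))^2
  fr <- seq_len(N) - 1L
  fr[fr >= N / 2] <- fr[fr >= N / 2] - N
  ky <- matrix(fr, N, N)         # row frequency
  kx <- matrix(fr, N, N, byrow = TRUE)
  r <- sqrt(kx^2 + ky^2)
  rmax <- min(N / period_range[1L], N / 2 - 1)
  ann <- r >= N / period_range[2L] & r <= rmax
  pw <- P[ann]
  if (background_subtract) {
    rb <- round(r[ann])
    pw <- pw - stats::ave(pw, rb, FUN = mean)
    pw[pw < 0] <- 0
  }
  if (sum(pw) <= 0) {
    attr(flat, "undefined") <- TRUE
    return(flat)
  }
  # wavevector angle + pi/2 = filament orientation, modulo pi
  th <- (atan2(ky[ann], kx[ann]) + pi / 2) %% pi
  bin <- pmin(floor(th / dtheta) + 1L, n_bins)
  dens <- numeric(n_bins)
  agg <- tapply(pw, bin, sum)
  dens[as.integer(names(agg))] <- agg
  dens <- dens / (sum(dens) * dtheta)
  structure(list(theta = theta_centers, p = dens),
            class = "orientation_spectrum")
}

#' Nematic tensor components from an orientation distribution
#'
#' `Qxx = integral p(theta) cos(2 theta) dtheta`,
#' `Qxy = integral p(theta) sin(2 theta) dtheta`. A distribution
#' concentrated at 90 degrees gives `(Qxx, Qxy) = (-1, 0)`; the scalar
#' order parameter used throughout is `Q = -Qxx` (positive for alignment
#' perpendicular to the x axis).
#'
#' @param spectrum an `orientation_spectrum` (or list with `theta` and a
#'   normalised density `p`).
#' @return named numeric vector `c(Qxx = , Qxy = )`.
#' @export
nematic_tensor_from_spectrum <- function(spectrum) {
  stopifnot(all(c("theta", "p") %in% names(spectrum)))
  dtheta <- pi / length(spectrum$theta)
  total <- sum(spectrum$p) * dtheta
  if (abs(total - 1) > 1e-6)
    stop("orientation distribution is not normalised (integral = ",
         format(total), ")")
  c(Qxx = sum(spectrum$p * cos(2 * spectrum$theta)) * dtheta,
    Qxy = sum(spectrum$p * sin(2 * spectrum$theta)) * dtheta)
}

#' Windowed nematic order tensor field of an image
#'
#' Slides a square window over the image (stride `stride_px`), optionally
#' equalises each window's intensities through their empirical CDF (rank
#' transform, making the result invariant to monotone intensity
#' rescaling), and computes per-window nematic tensor components from the
#' orientation spectrum.
#'
#' @param image intensity matrix (rows = y, cols = x).
#' @param window_px window side, px (default 32).
#' @param stride_px window stride, px (default 16).
#' @param cdf_equalize per-window histogram equalisation (default TRUE).
#' @param pixel_size micrometres per px (for the `x_um`, `y_um` columns;
#'   image centre at 0).
#' @param ... passed to [window_orientation_spectrum()].
#' @return data frame of class `orientation_field` with columns `x_px`,
#'   `y_px` (window centres), `x_um`, `y_um`, `Qxx`, `Qxy`, `theta`
#'   (dominant orientation, rad in `[0, pi)`) and `A` (nematic magnitude,
#'   `sqrt(Qxx^2 + Qxy^2) <= 1`).
#' @export
compute_nematic_field <- function(image, window_px = 32, stride_px = 16,
                                  cdf_equalize = TRUE, pixel_size = 0.1,
                                  ...) {
  stopifnot(is.matrix(image))
  H <- nrow(image); W <- ncol(image)
  if (H < window_px || W < window_px)
    stop("image smaller than the analysis window")
  ys <- seq(1L, H - window_px + 1L, by = stride_px)
  xs <- seq(1L, W - window_px + 1L, by = stride_px)
  grid <- expand.grid(y0 = ys, x0 = xs)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    y0 <- grid$y0[i]; x0 <- grid$x0[i]
    sub <- image[y0:(y0 + window_px - 1L), x0:(x0 + window_px - 1L)]
    if (cdf_equalize)
      sub <- matrix((rank(sub, ties.method = "average") - 0.5) /
                      length(sub), window_px, window_px)
    nematic_tensor_from_spectrum(window_orientation_spectrum(sub, ...))
  })
  Qxx <- vapply(res, `[[`, numeric(1L), "Qxx")
  Qxy <- vapply(res, `[[`, numeric(1L), "Qxy")
  x_px <- grid$x0 + (window_px - 1) / 2
  y_px <- grid$y0 + (window_px - 1) / 2
  out <- data.frame(x_px = x_px, y_px = y_px,
                    x_um = (x_px - (W + 1) / 2) * pixel_size,
                    y_um = (y_px - (H + 1) / 2) * pixel_size,
                    Qxx = Qxx, Qxy = Qxy,
                    theta = (0.5 * atan2(Qxy, Qxx)) %% pi,
                    A = sqrt(Qxx^2 + Qxy^2))
  class(out) <- c("orientation_field", "data.frame")
  out
}

#' Reduce an orientation field to an AP-axis nematic order profile
#'
#' Averages the tensor components over windows inside a band of y positions
#' at each x, returning the scalar order parameter `Q = -<Qxx>` (positive =
#' alignment orthogonal to the AP axis).
#'
#' @param field an `orientation_field` from [compute_nematic_field()].
#' @param y_band range of y (micrometres) to average over; default the full
#'   field.
#' @return data frame of class `nematic_profile` with columns `x` (um), `Q`
#'   and `Qxy`.
#' @export
nematic_profile <- function(field, y_band = NULL) {
  stopifnot(inherits(field, "orientation_field"))
  if (!is.null(y_band)) {
    field <- field[field$y_um >= y_band[1L] & field$y_um <= y_band[2L], ]
    if (nrow(field) == 0L) stop("empty y band")
  }
  agg <- stats::aggregate(cbind(Qxx, Qxy) ~ x_um, data = field, FUN = mean)
  out <- data.frame(x = agg$x_um, Q = -agg$Qxx, Qxy = agg$Qxy)
  class(out) <- c("nematic_profile", "data.frame")
  out
}
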