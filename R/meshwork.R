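# Synthetic filament-network images: seeded, growth-based meshworks with a
# controllable vertical orientation bias, plus image advection under a known
# flow (ground truth for the PIV and orientation pipelines).

#' Parameters for synthetic filament meshwork images
#'
#' Filaments are grown as persistent random walks seeded at uniform random
#' positions. Only the starting direction is biased: it is drawn from a
#' nematic von Mises distribution with density proportional to
#' `exp(B * cos(2 * (theta - pi/2)))`, concentrated toward vertical (90
#' degrees from the image x axis) for `B > 0` and uniform at `B = 0`.
#' Growth directions then wander by independent Gaussian increments, which
#' is why the measurable alignment saturates at large `B`.
#'
#' @param n_filaments filaments per image (>= 1).
#' @param bias_B orientation-bias strength, dimensionless (>= 0).
#' @param filament_length mean filament length, px.
#' @param step_length growth step, px.
#' @param angular_diffusion sd of the per-step direction increment, rad.
#' @param image_size `(height, width)` in px.
#' @param pixel_size micrometres per px.
#' @param psf_sigma Gaussian point-spread sigma, px.
#' @param snr peak signal-to-noise ratio (> 0): peak filament intensity over
#'   the background noise sd.
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   images.
#' @return an object of class `meshwork_params`.
#' @export
meshwork_params <- function(n_filaments = 100, bias_B = 0,
                            filament_length = 40, step_length = 2,
                            angular_diffusion = 0.15,
                            image_size = c(256, 256), pixel_size = 0.1,
                            psf_sigma = 1.5, snr = 10, seed = 1) {
  if (!is.numeric(n_filaments) || n_filaments < 1)
    stop("invalid parameter: n_filaments must be >= 1")
  if (!is.numeric(bias_B) || bias_B < 0)
    stop("invalid parameter: bias_B must be >= 0")
  if (!is.numeric(snr) || snr <= 0)
    stop("invalid parameter: snr must be > 0")
  if (length(image_size) != 2L || any(image_size < 1))
    stop("invalid parameter: image_size must be positive (H, W)")
  structure(list(n_filaments = as.integer(n_filaments), bias_B = bias_B,
                 filament_length = filament_length,
                 step_length = step_length,
                 angular_diffusion = angular_diffusion,
                 image_size = as.integer(image_size),
                 pixel_size = pixel_size, psf_sigma = psf_sigma,
                 snr = snr, seed = as.integer(seed)),
            class = "meshwork_params")
}

# Sample starting angles from density proportional to
# exp(B * cos(2*(theta - pi/2))) on [0, pi) by rejection from the uniform.
#' @noRd
sample_bias_angle <- function(n, B) {
  if (B == 0) return(stats::runif(n, 0, pi))
  out <- numeric(0)
  while (length(out) < n) {
    m <- 2L * (n - length(out)) + 10L
    th <- stats::runif(m, 0, pi)
    acc <- stats::runif(m) < exp(B * (cos(2 * (th - pi / 2)) - 1))
    out <- c(out, th[acc])
  }
  out[seq_len(n)]
}

# Deposit unit intensity at continuous positions into a matrix by bilinear
# splatting (rows = y, cols = x).
#' @noRd
splat <- function(img, xs, ys, w = 1) {
  H <- nrow(img); W <- ncol(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  for (k in 0:3) {
    dx <- k %% 2L; dy <- k %/% 2L
    xi <- x0 + dx; yi <- y0 + dy
    wt <- w * (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy)
    ok <- xi >= 1 & xi <= W & yi >= 1 & yi <= H & wt > 0
    if (any(ok)) {
      idx <- cbind(yi[ok], xi[ok])
      # accumulate (duplicated indices must add, not overwrite)
      v <- tapply(wt[ok], paste(idx[, 1L], idx[, 2L]), sum)
      ij <- do.call(rbind, strsplit(names(v), " "))
      img[cbind(as.integer(ij[, 1L]), as.integer(ij[, 2L]))] <-
        img[cbind(as.integer(ij[, 1L]), as.integer(ij[, 2L]))] + as.numeric(v)
    }
  }
  img
}

#' Generate a synthetic filament meshwork image
#'
#' Grows `n_filaments` persistent random walks (see [meshwork_params()]),
#' renders them with sub-pixel bilinear splatting, blurs with a Gaussian
#' point-spread function and adds Gaussian background noise scaled so that
#' the peak filament intensity divided by the background sd equals `snr`.
#'
#' @param params a [meshwork_params()] object.
#' @return intensity matrix (rows = y, cols = x) with `params` attached as
#'   attribute `params`; peak signal is normalised to 1.
#' @export
generate_filament_image <- function(params) {
  stopifnot(inherits(params, "meshwork_params"))
  H <- params$image_size[1L]; W <- params$image_size[2L]
  with_seed(params$seed, {
    n_steps <- max(1L, round(params$filament_length / params$step_length))
    sub <- max(1L, ceiling(params$step_length / 0.5))  # ~0.5 px render step
    dstep <- params$step_length / sub
    th0 <- sample_bias_angle(params$n_filaments, params$bias_B)
    pts <- vector("list", params$n_filaments)
    for (f in seq_len(params$n_filaments)) {
      # per-step heading with Gaussian wander, repeated for each sub-step
      th <- cumsum(c(th0[f],
                     stats::rnorm(n_steps - 1L, sd = params$angular_diffusion)))
      thsub <- rep(th, each = sub)
      xs <- stats::runif(1, 1, W) + cumsum(dstep * cos(thsub))
      ys <- stats::runif(1, 1, H) + cumsum(dstep * sin(thsub))
      pts[[f]] <- cbind(xs, ys)
    }
    all_pts <- do.call(rbind, pts)
    img <- splat(matrix(0, H, W), all_pts[, 1L], all_pts[, 2L], w = dstep)
    if (params$psf_sigma > 0)
      img <- EBImage::gblur(img, sigma = params$psf_sigma)
    peak <- stats::quantile(img[img > 0], 0.999, names = FALSE)
    if (!is.finite(peak) || peak <= 0) peak <- max(img, 1e-12)
    img <- img / peak
    img <- img + matrix(stats::rnorm(H * W, sd = 1 / params$snr), H, W)
    attr(img, "params") <- params
    img
  })
}

#' Advect an image by a one-dimensional flow field
#'
#' Warps the image along x by the displacement field `v(x) * dt` using a
#' semi-Lagrangian midpoint backtrace with bilinear interpolation. Image
#' columns are mapped to AP positions with the image centre at x = 0.
#'
#' @param image intensity matrix (rows = y, cols = x).
#' @param v_profile data frame with columns `x` (micrometres) and `v`
#'   (micrometres/min), e.g. from [generate_flow_profile()].
#' @param dt time interval, min.
#' @param pixel_size micrometres per px.
#' @return warped intensity matrix (regions advected in from outside the
#'   frame are 0).
#' @export
advect_image <- function(image, v_profile, dt, pixel_size) {
  stopifnot(is.matrix(image), all(c("x", "v") %in% names(v_profile)))
  H <- nrow(image); W <- ncol(image)
  xc <- (W + 1) / 2
  x_um <- (seq_len(W) - xc) * pixel_size
  vx <- interp_onto(v_profile$x, v_profile$v, x_um)
  if (max(abs(vx)) * dt / pixel_size >= W)
    stop("displacement exceeds image width")
  # midpoint backtrace: xs = x - dt * v(x - dt/2 * v(x))
  xmid <- x_um - 0.5 * dt * vx
  vmid <- interp_onto(v_profile$x, v_profile$v, xmid)
  xs_px <- (x_um - dt * vmid) / pixel_size + xc
  j0 <- floor(xs_px); fj <- xs_px - j0
  out <- matrix(0, H, W)
  colv <- function(j) {
    ok <- j >= 1 & j <= W
    m <- matrix(0, H, W)
    m[, ok] <- image[, j[ok], drop = FALSE]
    m
  }
  out <- colv(j0) * rep(1 - fj, each = H) + colv(j0 + 1L) * rep(fj, each = H)
  out
}
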