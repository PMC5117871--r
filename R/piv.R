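# Particle image velocimetry: windowed normalized cross-correlation with
# 3-point Gaussian subpixel refinement and neighborhood outlier replacement.

# Cross-correlation map of two equally sized windows via zero-padded FFT.
# Entry [dy, dx] (shift indices) estimates mean_a a(i,j) * b(i+dy, j+dx),
# normalised by the overlap area so finite-window tapering does not bias
# the peak toward zero shift.
#' @noRd
xcorr2 <- function(a, b, search) {
  N <- nrow(a); M <- 2L * N
  A <- matrix(0, M, M); B <- matrix(0, M, M)
  A[1:N, 1:N] <- a; B[1:N, 1:N] <- b
  C <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE)) / M^2
  sh <- -search:search
  idx <- (sh %% M) + 1L
  ov <- N - abs(sh)
  list(shifts = sh,
       C = C[idx, idx, drop = FALSE] * N^2 / outer(ov, ov))
}

# 3-point Gaussian subpixel peak refinement along one axis.
#' @noRd
gauss3 <- function(cm, c0, cp) {
  eps <- 1e-12
  lcm <- log(max(cm, eps)); lc0 <- log(max(c0, eps)); lcp <- log(max(cp, eps))
  den <- 2 * (lcm + lcp - 2 * lc0)
  if (!is.finite(den) || den >= 0) return(0)  # not a log-concave peak
  d <- (lcm - lcp) / den
  max(min(d, 0.5), -0.5)
}

#' Particle image velocimetry between two frames
#'
#' Estimates the displacement field from `frame_a` to `frame_b` by
#' normalised cross-correlation of interrogation windows (FFT-based, with
#' the peak search restricted to `search_px`), refined to subpixel accuracy
#' with a 3-point Gaussian fit along each axis, and converted to
#' micrometres per minute. Vectors whose normalised correlation peak falls
#' below `quality_min` are flagged invalid; vectors deviating from their
#' 3x3 neighbourhood median by more than 2 neighbourhood standard
#' deviations are replaced by that median.
#'
#' @param frame_a,frame_b intensity matrices of identical size.
#' @param window_px interrogation window side, px (default 32).
#' @param overlap window overlap fraction (default 0.5).
#' @param search_px maximum displacement searched, px (default 8).
#' @param dt frame interval, seconds.
#' @param pixel_size micrometres per px.
#' @param quality_min minimum normalised correlation for a valid vector
#'   (default 0.2).
#' @param outlier_filter apply the neighbourhood median replacement
#'   (default TRUE).
#' @return data frame of class `velocity_map` with window centres (`x_px`,
#'   `y_px`, `x_um`, `y_um`; micrometre origin at the image centre),
#'   velocities `vx`, `vy` (micrometres/min), `quality`, `valid` and
#'   `replaced`.
#' @export
piv <- function(frame_a, frame_b, window_px = 32, overlap = 0.5,
                search_px = 8, dt, pixel_size, quality_min = 0.2,
                outlier_filter = TRUE) {
  stopifnot(is.matrix(frame_a), identical(dim(frame_a), dim(frame_b)), dt > 0)
  H <- nrow(frame_a); W <- ncol(frame_a)
  if (window_px > min(H, W)) stop("interrogation window larger than frame")
  stride <- max(1L, round(window_px * (1 - overlap)))
  ys <- seq(1L, H - window_px + 1L, by = stride)
  xs <- seq(1L, W - window_px + 1L, by = stride)
  grid <- expand.grid(y0 = ys, x0 = xs)
  n <- nrow(grid)
  dxs <- dys <- qual <- numeric(n)
  for (i in seq_len(n)) {
    ry <- grid$y0[i]:(grid$y0[i] + window_px - 1L)
    rx <- grid$x0[i]:(grid$x0[i] + window_px - 1L)
    a <- frame_a[ry, rx]; b <- frame_b[ry, rx]
    a <- a - mean(a); b <- b - mean(b)
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na < 1e-12 || nb < 1e-12) { qual[i] <- 0; next }
    cc <- xcorr2(a, b, search_px)
    pk <- which(cc$C == max(cc$C), arr.ind = TRUE)[1L, ]
    qual[i] <- cc$C[pk[1L], pk[2L]] / (na * nb)
    dy <- cc$shifts[pk[1L]]; dx <- cc$shifts[pk[2L]]
    m <- length(cc$shifts)
    if (pk[1L] > 1L && pk[1L] < m)
      dy <- dy + gauss3(cc$C[pk[1L] - 1L, pk[2L]], cc$C[pk[1L], pk[2L]],
                        cc$C[pk[1L] + 1L, pk[2L]])
    if (pk[2L] > 1L && pk[2L] < m)
      dx <- dx + gauss3(cc$C[pk[1L], pk[2L] - 1L], cc$C[pk[1L], pk[2L]],
                        cc$C[pk[1L], pk[2L] + 1L])
    dxs[i] <- dx; dys[i] <- dy
  }
  px_per_min <- 60 / dt  # displacement px -> px/min
  vx <- dxs * px_per_min * pixel_size
  vy <- dys * px_per_min * pixel_size
  valid <- qual >= quality_min
  replaced <- rep(FALSE, n)
  if (outlier_filter) {
    vxm <- matrix(vx, length(ys), length(xs))
    vym <- matrix(vy, length(ys), length(xs))
    vm <- matrix(valid, length(ys), length(xs))
    for (comp in 1:2) {
      V <- if (comp == 1L) vxm else vym
      Vnew <- V
      for (r in seq_len(nrow(V))) for (cc2 in seq_len(ncol(V))) {
        nb_r <- max(1L, r - 1L):min(nrow(V), r + 1L)
        nb_c <- max(1L, cc2 - 1L):min(ncol(V), cc2 + 1L)
        nbv <- V[nb_r, nb_c][vm[nb_r, nb_c]]
        nbv <- nbv[!is.na(nbv)]
        if (length(nbv) < 3L) next
        med <- stats::median(nbv); s <- stats::sd(nbv)
        if (is.finite(s) && s > 1e-9 && abs(V[r, cc2] - med) > 2 * s) {
          Vnew[r, cc2] <- med
          replaced[(cc2 - 1L) * nrow(V) + r] <- TRUE
        }
      }
      if (comp == 1L) vxm <- Vnew else vym <- Vnew
    }
    vx <- as.numeric(vxm); vy <- as.numeric(vym)
  }
  x_px <- grid$x0 + (window_px - 1) / 2
  y_px <- grid$y0 + (window_px - 1) / 2
  out <- data.frame(x_px = x_px, y_px = y_px,
                    x_um = (x_px - (W + 1) / 2) * pixel_size,
                    y_um = (y_px - (H + 1) / 2) * pixel_size,
                    vx = vx, vy = vy, quality = qual,
                    valid = valid, replaced = replaced)
  class(out) <- c("velocity_map", "data.frame")
  out
}

#' Average a velocity map into an AP-axis velocity profile
#'
#' Band-averages the x velocity component over valid vectors at each x;
#' columns with no valid vector are returned as `NA` (marked missing).
#'
#' @param map a `velocity_map` from [piv()].
#' @param y_band optional y range (micrometres) to average over.
#' @return data frame of class `velocity_profile` with columns `x`
#'   (micrometres), `v` (micrometres/min) and `n_valid`.
#' @export
velocity_profile <- function(map, y_band = NULL) {
  stopifnot(inherits(map, "velocity_map"))
  if (!is.null(y_band)) {
    map <- map[map$y_um >= y_band[1L] & map$y_um <= y_band[2L], ]
    if (nrow(map) == 0L) stop("empty y band")
  }
  xs <- sort(unique(map$x_um))
  v <- vapply(xs, function(x) {
    vv <- map$vx[map$x_um == x & map$valid]
    if (length(vv) == 0L) NA_real_ else mean(vv)
  }, numeric(1L))
  nv <- vapply(xs, function(x) sum(map$x_um == x & map$valid), integer(1L))
  out <- data.frame(x = xs, v = v, n_valid = nv)
  class(out) <- c("velocity_profile", "data.frame")
  out
}
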