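# Furrow ingression: extraction of outer ingression profiles relative to
# the eggshell, anisotropic active tension profiles, and a small-deformation
# prediction of ingression with a single shared scale parameter.

#' Outer ingression profile from a mid-plane contour
#'
#' The outer ingression distance is the inward displacement of the cortex
#' from the rigid eggshell, `u(x) = R0(x) - r(x)`, clipped at 0.
#'
#' @param contour data frame with columns `x` (micrometres), `r` (cortex
#'   mid-plane radius, micrometres) and `R0` (eggshell reference radius,
#'   micrometres); requires `0 < r <= R0` up to measurement noise.
#' @param smooth_sigma optional Gaussian smoothing of `u`, micrometres
#'   (default 0).
#' @param tol tolerance on `r > R0` violations before erroring (default
#'   1e-6 micrometres).
#' @return data frame of class `ingression_profile` with columns `x` and
#'   `u` (micrometres, >= 0).
#' @export
extract_ingression_profile <- function(contour, smooth_sigma = 0,
                                       tol = 1e-6) {
  stopifnot(all(c("x", "r", "R0") %in% names(contour)))
  if (any(contour$r <= 0)) stop("contract violation: non-positive radius")
  if (any(contour$r > contour$R0 + tol))
    stop("contract violation: cortex radius exceeds the eggshell reference")
  u <- pmax(contour$R0 - contour$r, 0)
  if (smooth_sigma > 0) {
    dx <- grid_dx(contour$x)
    u <- pmax(gauss_smooth1d(u, smooth_sigma / dx), 0)
  }
  out <- data.frame(x = contour$x, u = u)
  class(out) <- c("ingression_profile", "data.frame")
  out
}

#' Anisotropic active cortical tension profiles
#'
#' Builds the AP (`t_ss`) and circumferential (`t_phiphi`) cortical tension
#' profiles from myosin, flow and nematic order: an isotropic active part
#' proportional to the myosin concentration `c/c0` shared by both
#' components, a viscous part proportional to the velocity gradient added
#' to the AP component, and an anisotropic active part `p3 * Q` added to
#' the circumferential and subtracted from the AP component (positive Q =
#' circumferential filament alignment increases circumferential tension).
#' With `p3 = 0` the tension is isotropic (`t_ss == t_phiphi`) whatever Q.
#'
#' @param c_prof myosin concentration profile (arbitrary units, >= 0).
#' @param dvdx velocity gradient profile, 1/min.
#' @param Q nematic order profile.
#' @param p3 anisotropic active tension coefficient (model units per unit
#'   Q).
#' @param active_scale coefficient of the isotropic active part (default 1).
#' @param viscous_scale coefficient of the viscous part (default 0.1 model
#'   units per min).
#' @param c0 myosin normalisation (default the spatial mean of `c_prof`).
#' @return data frame of class `tension_profiles` with columns `t_ss`,
#'   `t_phiphi` and the three parts (`iso`, `visc`, `aniso`).
#' @export
active_tension_profiles <- function(c_prof, dvdx, Q, p3,
                                    active_scale = 1, viscous_scale = 0.1,
                                    c0 = NULL) {
  n <- length(c_prof)
  stopifnot(length(dvdx) == n, length(Q) == n)
  if (is.null(c0)) c0 <- mean(c_prof)
  iso <- active_scale * c_prof / c0
  visc <- viscous_scale * dvdx
  aniso <- p3 * Q
  out <- data.frame(iso = iso, visc = visc, aniso = aniso,
                    t_ss = iso + visc - aniso,
                    t_phiphi = iso + aniso)
  class(out) <- c("tension_profiles", "data.frame")
  out
}

# Inward normal traction excess of a nearly cylindrical cortex confined by
# the eggshell: circumferential tension over the local radius plus the
# AP-tension times the meridional curvature of the reference shape.
#' @noRd
normal_traction <- function(x, tens, R0) {
  dx <- grid_dx(x)
  kap <- rep(0, length(x))
  i <- 2:(length(x) - 1L)
  d1 <- grad1d(R0, dx)
  kap[i] <- -(R0[i + 1L] - 2 * R0[i] + R0[i - 1L]) / dx^2 /
    (1 + d1[i]^2)^1.5
  tens$t_phiphi / R0 + tens$t_ss * kap
}

#' Predict the outer ingression profile from tension anisotropy
#'
#' Small-deformation treatment of an axisymmetric cortex confined by a
#' rigid eggshell: the inward normal traction is computed from the
#' circumferential tension over the local radius plus the AP tension times
#' the meridional curvature of the reference shape; where the traction
#' exceeds its confinement-balancing baseline (the spatial mean over the
#' fit region) the cortex detaches inward by a distance proportional to
#' the excess, and the profile is 0 where the cortex presses against the
#' shell. The map is linear in `global_scale` and reduces exactly to the
#' isotropic model at `p3 = 0`.
#'
#' @param c_prof,dvdx,Q aligned profiles on `x` (see
#'   [active_tension_profiles()]).
#' @param x AP grid, micrometres.
#' @param R0 eggshell reference radius profile, micrometres (> 0); scalar
#'   values are recycled.
#' @param p3 anisotropic tension coefficient.
#' @param global_scale the single fitted scale converting traction excess
#'   to micrometres of ingression.
#' @param fit_region region over which the baseline is computed,
#'   micrometres.
#' @param ... passed to [active_tension_profiles()].
#' @return data frame of class `ingression_profile` with columns `x`, `u`.
#' @export
predict_ingression <- function(c_prof, dvdx, Q, x, R0 = 15, p3 = 0,
                               global_scale = 1, fit_region = c(-15, 15),
                               ...) {
  assert_grid(x)
  if (length(R0) == 1L) R0 <- rep(R0, length(x))
  if (any(R0 <= 0)) stop("non-physical negative or zero reference radius")
  tens <- active_tension_profiles(c_prof, dvdx, Q, p3 = p3, ...)
  tr <- normal_traction(x, tens, R0)
  keep <- x >= fit_region[1L] & x <= fit_region[2L]
  base <- mean(tr[keep])
  out <- data.frame(x = x, u = global_scale * pmax(tr - base, 0))
  class(out) <- c("ingression_profile", "data.frame")
  out
}

#' Fit the shared ingression scale across pseudocleavage and cytokinesis
#'
#' Finds the single scale parameter that best converts predicted traction
#' excess into the measured outer ingression simultaneously for both
#' stages (summed residual sum of squares), optionally also fitting the
#' anisotropic coefficient `p3`. The isotropic control (`p3 = 0`) is
#' always fitted and reported alongside.
#'
#' @param datasets named list with elements `pseudocleavage` and
#'   `cytokinesis`, each a list (or [embryo_dataset()]) with `x`, `c_prof`,
#'   `dvdx`, `Q` and the measured ingression `u`, plus optionally `R0`.
#' @param p3_mode `"fit"` (default) to optimise `p3`, or a fixed numeric
#'   value.
#' @param p3_range search interval for `p3` when fitted (default
#'   `c(0, 10)`).
#' @param ... passed to [predict_ingression()].
#' @return list of class `ingression_fit`: `global_scale`, `p3`, `rss`,
#'   `rss_isotropic` (the `p3 = 0` control), `scale_isotropic`,
#'   `predicted` (per-stage profiles), `predicted_isotropic`.
#' @export
fit_ingression_parameter <- function(datasets, p3_mode = "fit",
                                     p3_range = c(0, 10), ...) {
  stopifnot(all(c("pseudocleavage", "cytokinesis") %in% names(datasets)))
  for (d in datasets)
    if (is.null(d$u) || length(d$u) == 0L) stop("empty ingression dataset")
  unit_preds <- function(p3)
    lapply(datasets, function(d)
      predict_ingression(d$c_prof, d$dvdx, d$Q, d$x,
                         R0 = if (is.null(d$R0)) 15 else d$R0,
                         p3 = p3, global_scale = 1, ...)$u)
  # scale is profiled in closed form: s = <pred, u> / <pred, pred>
  eval_p3 <- function(p3) {
    up <- unit_preds(p3)
    num <- sum(mapply(function(p, d) sum(p * d$u), up, datasets))
    den <- sum(vapply(up, function(p) sum(p^2), numeric(1L)))
    s <- if (den > 0) max(num / den, 0) else 0
    rss <- sum(mapply(function(p, d) sum((s * p - d$u)^2), up, datasets))
    list(scale = s, rss = rss, unit = up)
  }
  iso <- eval_p3(0)
  if (identical(p3_mode, "fit")) {
    opt <- stats::optimize(function(p3) eval_p3(p3)$rss,
                           interval = p3_range, tol = 1e-8)
    p3 <- opt$minimum
    best <- eval_p3(p3)
    if (iso$rss <= best$rss) { p3 <- 0; best <- iso }
  } else {
    p3 <- as.numeric(p3_mode)
    best <- eval_p3(p3)
  }
  mk <- function(ev) mapply(function(p, d)
    structure(data.frame(x = d$x, u = ev$scale * p),
              class = c("ingression_profile", "data.frame")),
    ev$unit, datasets, SIMPLIFY = FALSE)
  structure(list(global_scale = best$scale, p3 = p3, rss = best$rss,
                 rss_isotropic = iso$rss, scale_isotropic = iso$scale,
                 predicted = mk(best), predicted_isotropic = mk(iso)),
            class = "ingression_fit")
}
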