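#' Material parameters of the active nematic gel model
#'
#' Container for the one-dimensional active nematic gel model of the cell
#' cortex. The steady-state nematic order profile Q(x) obeys
#' \deqn{Q = -\tau v \partial_x Q - \frac{\beta\tau}{2}\partial_x v
#'       + \ell^2 \partial_x^2 Q + \lambda'\tau \frac{c(x)}{c_0} Q}
#' where v(x) is the cortical flow (micrometres/min), c(x) the myosin
#' concentration and Q dimensionless. The fitted quantities are the products
#' `beta_tau` (flow-alignment coupling times relaxation time, min) and
#' `lambda_tau` (myosin-coupled active alignment, dimensionless), the
#' relaxation time `tau` (min), the alignment length `ell` (micrometres),
#' and the Dirichlet boundary values `C1` (left) and `C2` (right) of Q at
#' the fit-domain edges.
#'
#' @param tau relaxation time of nematic order, min (>= 0).
#' @param beta_tau product of the flow-alignment coupling and tau, min (>= 0).
#' @param ell alignment length, micrometres (> 0).
#' @param lambda_tau myosin-coupled active-alignment product, dimensionless
#'   (>= 0); the active term is `lambda_tau * c(x)/c0 * Q` and is switched
#'   off when no myosin profile is supplied.
#' @param C1,C2 boundary values of Q at the left and right domain edges.
#' @return an object of class `gel_parameters`.
#' @export
gel_parameters <- function(tau, beta_tau, ell, lambda_tau = 0, C1 = 0, C2 = 0) {
  stopifnot(is.numeric(tau), tau >= 0, is.numeric(beta_tau),
            is.numeric(ell), ell > 0, is.numeric(lambda_tau), lambda_tau >= 0)
  structure(list(tau = tau, beta_tau = beta_tau, ell = ell,
                 lambda_tau = lambda_tau, C1 = C1, C2 = C2),
            class = "gel_parameters")
}

#' @export
print.gel_parameters <- function(x, ...) {
  cat("Active nematic gel parameters:\n")
  cat(sprintf("  tau        = %.4g min\n", x$tau))
  cat(sprintf("  beta*tau   = %.4g min\n", x$beta_tau))
  cat(sprintf("  ell        = %.4g um\n", x$ell))
  if (x$lambda_tau != 0)
    cat(sprintf("  lambda'*tau= %.4g\n", x$lambda_tau))
  cat(sprintf("  C1, C2     = %.4g, %.4g\n", x$C1, x$C2))
  invisible(x)
}

# Relaxation coefficient a(x) = 1 - lambda_tau * c/c0; errors on instability.
#' @noRd
relax_coef <- function(n, lambda_tau, c_prof, c0) {
  if (is.null(c_prof) || lambda_tau == 0) return(rep(1, n))
  if (is.null(c0)) c0 <- mean(c_prof)
  a <- 1 - lambda_tau * c_prof / c0
  if (any(a <= 0))
    stop("instability: 1 - lambda_tau * c(x)/c0 <= 0 somewhere on the domain")
  a
}

# Assemble the steady-state operator L[Q] = ell^2 Q'' - tau v Q' - a Q as a
# sparse tridiagonal matrix with Dirichlet boundary rows, on a uniform grid.
#' @noRd
steady_operator <- function(v, dx, tau, ell, a) {
  n <- length(v)
  diffu <- ell^2 / dx^2
  adv <- tau * v / (2 * dx)
  main <- c(1, rep(-2 * diffu, n - 2L) - a[2:(n - 1L)], 1)
  lower <- c(diffu + adv[2:(n - 1L)], 0)           # entries (i, i-1)
  upper <- c(0, diffu - adv[2:(n - 1L)])           # entries (i, i+1)
  Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
                     diagonals = list(lower, main, upper))
}

# Refine a uniform grid to spacing <= refine_dx and interpolate inputs.
#' @noRd
refine_inputs <- function(x, profiles, refine_dx) {
  if (is.null(refine_dx)) return(c(list(x = x), profiles))
  span <- diff(range(x))
  n <- max(length(x) - 1L, ceiling(span / refine_dx))
  xf <- seq(min(x), max(x), length.out = n + 1L)
  out <- lapply(profiles, function(p) if (is.null(p)) NULL else interp_onto(x, p, xf))
  c(list(x = xf), out)
}

#' Solve the steady-state nematic order boundary-value problem
#'
#' Solves the linear two-point boundary-value problem
#' `ell^2 Q'' - tau v Q' - (1 - lambda_tau c/c0) Q = (beta_tau/2) dvdx`
#' with Dirichlet values `C1`, `C2` at the grid ends, by centred second-order
#' finite differences on a grid refined to spacing at most `refine_dx`
#' (linear interpolation of the inputs), with a direct sparse tridiagonal
#' solve.
#'
#' @param x strictly increasing, uniformly spaced AP positions (micrometres).
#' @param v flow velocity on `x` (micrometres/min).
#' @param dvdx velocity gradient on `x` (1/min).
#' @param params a [gel_parameters()] object.
#' @param c_prof optional myosin concentration profile on `x`; when absent
#'   the active-alignment term is off regardless of `lambda_tau`.
#' @param c0 normalisation for the myosin profile; defaults to its spatial
#'   mean over the domain.
#' @param refine_dx target grid spacing for the solve, micrometres
#'   (default 0.25, enough to resolve alignment lengths down to ~1.7
#'   micrometres); `NULL` solves on the data grid as given.
#' @return numeric Q(x) on the input grid. The refined-grid solution is
#'   attached as attributes `x_fine` and `Q_fine`.
#' @examples
#' # Uniform compression -dv/dx = k with matched boundaries gives the
#' # closed form Q = beta_tau * k / 2 everywhere:
#' x <- seq(-15, 15, by = 0.5)
#' k <- 0.4
#' p <- gel_parameters(tau = 1, beta_tau = 0.6, ell = 2,
#'                     C1 = 0.6 * k / 2, C2 = 0.6 * k / 2)
#' Q <- solve_steady_Q(x, v = -k * x, dvdx = rep(-k, length(x)), params = p)
#' all.equal(Q, rep(0.12, length(x)), tolerance = 1e-8)
#' @export
solve_steady_Q <- function(x, v, dvdx, params, c_prof = NULL, c0 = NULL,
                           refine_dx = 0.25) {
  stopifnot(inherits(params, "gel_parameters"))
  assert_grid(x)
  stopifnot(length(v) == length(x), length(dvdx) == length(x))
  fine <- refine_inputs(x, list(v = v, dvdx = dvdx, c_prof = c_prof), refine_dx)
  if (!is.null(c_prof) && is.null(c0)) c0 <- mean(c_prof)
  dx <- grid_dx(fine$x)
  n <- length(fine$x)
  if (n < 3L) stop("grid too short for the boundary-value problem")
  a <- relax_coef(n, params$lambda_tau, fine$c_prof, c0)
  A <- steady_operator(fine$v, dx, params$tau, params$ell, a)
  rhs <- c(params$C1, (params$beta_tau / 2) * fine$dvdx[2:(n - 1L)], params$C2)
  Qf <- as.numeric(Matrix::solve(A, rhs))
  Q <- interp_onto(fine$x, Qf, x)
  attr(Q, "x_fine") <- fine$x
  attr(Q, "Q_fine") <- Qf
  Q
}

# Affine basis of the steady solution at fixed (tau, ell, lambda_tau):
# Q = beta_tau * Qb + C1 * Q1 + C2 * Q2. Used to profile the linear
# parameters out of the least-squares fit exactly.
#' @noRd
steady_basis <- function(x, v, dvdx, tau, ell, lambda_tau = 0,
                         c_prof = NULL, c0 = NULL, refine_dx = 0.25) {
  fine <- refine_inputs(x, list(v = v, dvdx = dvdx, c_prof = c_prof), refine_dx)
  if (!is.null(c_prof) && is.null(c0)) c0 <- mean(c_prof)
  dx <- grid_dx(fine$x)
  n <- length(fine$x)
  a <- relax_coef(n, lambda_tau, fine$c_prof, c0)
  A <- steady_operator(fine$v, dx, tau, ell, a)
  rhs <- cbind(c(0, fine$dvdx[2:(n - 1L)] / 2, 0),
               c(1, rep(0, n - 1L)),
               c(rep(0, n - 1L), 1))
  B <- as.matrix(Matrix::solve(A, rhs))
  apply(B, 2L, function(col) interp_onto(fine$x, col, x))
}

#' Time-step the dynamic nematic order equation
#'
#' Integrates `dQ/dt = -v dQ/dx - (beta/2) dvdx - a(x) Q / tau
#' + (ell^2/tau) d2Q/dx2` (with `a(x) = 1 - lambda_tau c/c0`, `beta =
#' beta_tau / tau`) under a static flow field, with Dirichlet boundaries
#' held at the initial values.
#'
#' Two advection schemes are available: `"upwind"` treats advection
#' explicitly with first-order upwinding (requires a CFL-respecting `dt`),
#' while `"centered"` folds a centred advection stencil into the implicit
#' solve, making the scheme's fixed point identical to the
#' [solve_steady_Q()] discretisation on the same grid. Relaxation and
#' diffusion are always implicit (backward Euler).
#'
#' @inheritParams solve_steady_Q
#' @param Q0 initial nematic order profile on `x`; its end values are held
#'   as boundary conditions.
#' @param dt time step, min.
#' @param t_end total integration time, min.
#' @param advection `"upwind"` (default) or `"centered"`.
#' @param save_every store the profile every this many steps (default:
#'   final state only).
#' @return list with `x`, `times` (min), `Q` (matrix, one column per saved
#'   time) and `final` (profile at `t_end`).
#' @export
simulate_Q_dynamics <- function(x, v, dvdx, params, Q0, dt, t_end,
                                c_prof = NULL, c0 = NULL,
                                advection = c("upwind", "centered"),
                                save_every = NULL) {
  stopifnot(inherits(params, "gel_parameters"))
  advection <- match.arg(advection)
  assert_grid(x)
  n <- length(x)
  stopifnot(length(v) == n, length(dvdx) == n, length(Q0) == n, dt > 0)
  dx <- grid_dx(x)
  if (params$tau <= 0) stop("dynamic simulation requires tau > 0")
  if (advection == "upwind" && max(abs(v)) * dt > dx)
    stop(sprintf("CFL violation: max|v|*dt = %.3g exceeds dx = %.3g",
                 max(abs(v)) * dt, dx))
  if (!is.null(c_prof) && is.null(c0)) c0 <- mean(c_prof)
  a <- relax_coef(n, params$lambda_tau, c_prof, c0)
  tau <- params$tau; ell <- params$ell
  beta <- params$beta_tau / tau

  diffu <- dt * ell^2 / (tau * dx^2)
  main <- c(1, 1 + dt * a[2:(n - 1L)] / tau + 2 * diffu, 1)
  lower <- rep(-diffu, n - 1L); lower[n - 1L] <- 0
  upper <- rep(-diffu, n - 1L); upper[1L] <- 0
  if (advection == "centered") {
    adv <- dt * v[2:(n - 1L)] / (2 * dx)
    lower[1:(n - 2L)] <- lower[1:(n - 2L)] - adv
    upper[2:(n - 1L)] <- upper[2:(n - 1L)] + adv
  }
  M <- Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
                          diagonals = list(lower, main, upper))
  Mf <- Matrix::lu(M)

  nsteps <- ceiling(t_end / dt)
  keep <- if (is.null(save_every)) integer(0) else seq(save_every, nsteps, by = save_every)
  saved <- matrix(NA_real_, n, length(keep))
  times <- keep * dt
  Q <- Q0
  src <- -(beta / 2) * dvdx
  for (s in seq_len(nsteps)) {
    rhs <- Q + dt * src
    if (advection == "upwind") {
      gfwd <- c(diff(Q) / dx, 0)
      gbwd <- c(0, diff(Q) / dx)
      rhs <- rhs - dt * v * ifelse(v > 0, gbwd, gfwd)
    }
    rhs[1L] <- Q0[1L]; rhs[n] <- Q0[n]
    Q <- as.numeric(Matrix::solve(Mf, rhs))
    j <- match(s, keep)
    if (!is.na(j)) saved[, j] <- Q
  }
  list(x = x, times = times, Q = saved, final = Q)
}

#' Decompose steady-state nematic order into its mechanistic terms
#'
#' Splits the steady-state identity
#' `Q = -(beta_tau/2) dvdx - tau v dQ/dx + ell^2 d2Q/dx2 + lambda_tau (c/c0) Q`
#' into its four contributions, evaluated with the same finite-difference
#' stencils as the solver so the terms sum to Q exactly at interior points.
#' The solve is performed on the supplied grid (no refinement) so the
#' discrete identity holds on the returned profiles.
#'
#' @inheritParams solve_steady_Q
#' @param Q optional nematic order profile on `x`; solved from the model
#'   when absent.
#' @return data frame with columns `x`, `Q`, `compression`
#'   (`-(beta_tau/2) dvdx`), `advection` (`-tau v dQ/dx`), `diffusion`
#'   (`ell^2 d2Q/dx2`) and `active` (`lambda_tau (c/c0) Q`). Derivative
#'   terms are `NA` at the two boundary points.
#' @export
decompose_alignment_terms <- function(x, v, dvdx, params, Q = NULL,
                                      c_prof = NULL, c0 = NULL) {
  stopifnot(inherits(params, "gel_parameters"))
  assert_grid(x)
  if (is.null(Q))
    Q <- solve_steady_Q(x, v, dvdx, params, c_prof = c_prof, c0 = c0,
                        refine_dx = NULL)
  dx <- grid_dx(x)
  n <- length(x)
  i <- 2:(n - 1L)
  dQ <- d2Q <- rep(NA_real_, n)
  dQ[i] <- (Q[i + 1L] - Q[i - 1L]) / (2 * dx)
  d2Q[i] <- (Q[i + 1L] - 2 * Q[i] + Q[i - 1L]) / dx^2
  act <- rep(0, n)
  if (!is.null(c_prof) && params$lambda_tau != 0) {
    if (is.null(c0)) c0 <- mean(c_prof)
    act <- params$lambda_tau * c_prof / c0 * Q
  }
  data.frame(x = x, Q = as.numeric(Q),
             compression = -(params$beta_tau / 2) * dvdx,
             advection = -params$tau * v * dQ,
             diffusion = params$ell^2 * d2Q,
             active = act)
}
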