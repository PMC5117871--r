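# Steady-state BVP solver, dynamic integrator and term decomposition.

test_that("uniform compression with matched boundaries gives the constant closed form", {
  x <- seq(-15, 15, by = 0.5)
  cases <- list(c(k = 0.4, bt = 0.6), c(k = 0.7, bt = 0.654), c(k = 0.2, bt = 1.3))
  for (cs in cases) {
    qc <- cs[["bt"]] * cs[["k"]] / 2
    p <- gel_parameters(tau = 1.7, beta_tau = cs[["bt"]], ell = 2.2,
                        C1 = qc, C2 = qc)
    Q <- solve_steady_Q(x, v = -cs[["k"]] * x, dvdx = rep(-cs[["k"]], length(x)),
                        params = p)
    expect_lt(max(abs(Q - qc)), 1e-6)
  }
})

test_that("zero flow and zero boundaries give Q identically zero", {
  x <- seq(-15, 15, by = 0.5)
  p <- gel_parameters(tau = 2, beta_tau = 0.6, ell = 2, C1 = 0, C2 = 0)
  Q <- solve_steady_Q(x, rep(0, 61), rep(0, 61), p)
  expect_equal(max(abs(Q)), 0, tolerance = 1e-12)
})

test_that("solver matches an independent fine-grid shooting integrator", {
  # linear BVP solved by superposition of two initial-value integrations
  shoot_Q <- function(x, v_fun, dvdx_fun, params) {
    deriv <- function(s, y, parms)
      list(c(y[2],
             (params$tau * v_fun(s) * y[2] + y[1] +
                (params$beta_tau / 2) * dvdx_fun(s)) / params$ell^2))
    iv <- function(P0)
      deSolve::lsoda(c(params$C1, P0), x, deriv, NULL,
                     rtol = 1e-10, atol = 1e-12)[, 2]
    y0 <- iv(0); y1 <- iv(1)
    s <- (params$C2 - y0[length(x)]) / (y1[length(x)] - y0[length(x)])
    y0 + s * (y1 - y0)
  }
  x <- seq(-15, 15, by = 0.05)   # inputs sampled on the fine grid directly
  A <- 5.77; ctr <- 5; w <- 5
  v_fun <- function(s) -A * exp(-(s - ctr)^2 / (2 * w^2))
  dvdx_fun <- function(s) A * (s - ctr) / w^2 * exp(-(s - ctr)^2 / (2 * w^2))
  p <- gel_parameters(tau = 2.34, beta_tau = 0.654, ell = 1.69,
                      C1 = 0.05, C2 = 0.05)
  Q_ref <- shoot_Q(x, v_fun, dvdx_fun, p)
  Q <- solve_steady_Q(x, v_fun(x), dvdx_fun(x), p, refine_dx = NULL)
  expect_lt(max(abs(Q - Q_ref)), 1e-4)
})

test_that("steady solution is affine in boundary values and linear in beta_tau", {
  vp <- generate_flow_profile(cyto_flow())
  base <- function(bt, C1, C2)
    as.numeric(solve_steady_Q(vp$x, vp$v, vp$dvdx,
      gel_parameters(2.34, bt, 1.69, C1 = C1, C2 = C2)))
  Q00 <- base(0, 0, 0)
  Qb <- base(1, 0, 0); Q1 <- base(0, 1, 0); Q2 <- base(0, 0, 1)
  for (coefs in list(c(0.654, 0.05, 0.05), c(2, -0.1, 0.3))) {
    lhs <- base(coefs[1], coefs[2], coefs[3])
    rhs <- coefs[1] * Qb + coefs[2] * Q1 + coefs[3] * Q2
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  expect_lt(max(abs(Q00)), 1e-12)
})

test_that("instability of the active term raises an explicit error", {
  vp <- generate_flow_profile(cyto_flow())
  cprof <- 1 + 5 * exp(-vp$x^2 / 18)   # strong band: 1 - lambda*c/c0 < 0
  p <- gel_parameters(2.34, 0.654, 1.69, lambda_tau = 0.8, C1 = 0, C2 = 0)
  expect_error(solve_steady_Q(vp$x, vp$v, vp$dvdx, p, c_prof = cprof),
               "instability")
})

test_that("dynamics relax exponentially and obey the CFL guard", {
  x <- seq(-15, 15, by = 0.5)
  z <- rep(0, length(x))
  p <- gel_parameters(tau = 2, beta_tau = 0.6, ell = 2, C1 = 0.1, C2 = 0.1)
  sim <- simulate_Q_dynamics(x, z, z, p, Q0 = rep(0.1, length(x)),
                             dt = 0.005, t_end = 1)
  # boundary pinning spreads over ~sqrt(ell^2 t / tau); check at the centre
  expect_equal(sim$final[31], 0.1 * exp(-1 / 2), tolerance = 1e-3)
  expect_error(
    simulate_Q_dynamics(x, rep(10, length(x)), z, p, Q0 = z,
                        dt = 1, t_end = 2),
    "CFL")
})

test_that("dynamics converge to the steady-state solution for static flow", {
  vp <- generate_flow_profile(cyto_flow())
  p <- cyto_truth()
  Qs <- solve_steady_Q(vp$x, vp$v, vp$dvdx, p, refine_dx = NULL)
  Q0 <- rep(0.05, length(vp$x))
  sim <- simulate_Q_dynamics(vp$x, vp$v, vp$dvdx, p, Q0 = Q0,
                             dt = 0.02, t_end = 40, advection = "centered")
  expect_lt(max(abs(sim$final - Qs)), 1e-4)
  # upwinding converges to the same solution at first order in dx
  simu <- simulate_Q_dynamics(vp$x, vp$v, vp$dvdx, p, Q0 = Q0,
                              dt = 0.02, t_end = 40, advection = "upwind")
  vpf <- generate_flow_profile(cyto_flow(grid = seq(-15, 15, by = 0.125)))
  Qsf <- solve_steady_Q(vpf$x, vpf$v, vpf$dvdx, p, refine_dx = NULL)
  simf <- simulate_Q_dynamics(vpf$x, vpf$v, vpf$dvdx, p,
                              Q0 = rep(0.05, length(vpf$x)),
                              dt = 0.005, t_end = 40, advection = "upwind")
  err_coarse <- max(abs(simu$final - Qs))
  err_fine <- max(abs(simf$final - Qsf))
  expect_lt(err_fine, err_coarse / 2.5)   # ~4x expected for 4x finer grid
})

test_that("advection limit transports a bump at the flow speed", {
  # ell -> 0, tau -> large: pure advection of the initial profile
  x <- seq(-30, 30, by = 0.25)
  v <- rep(2, length(x)); z <- rep(0, length(x))
  p <- gel_parameters(tau = 1e4, beta_tau = 0, ell = 0.05, C1 = 0, C2 = 0)
  Q0 <- 0.3 * exp(-(x + 10)^2 / 8)
  sim <- simulate_Q_dynamics(x, v, z, p, Q0 = Q0, dt = 0.05, t_end = 5)
  expected <- 0.3 * exp(-(x + 10 - 2 * 5)^2 / 8)
  expect_lt(max(abs(sim$final - expected)), 0.05)  # numerical diffusion bound
})

test_that("alignment terms sum to Q and the active term vanishes without myosin coupling", {
  vp <- generate_flow_profile(cyto_flow())
  cprof <- 1 + 2 * exp(-vp$x^2 / 18)
  p <- cyto_truth(lambda_tau = 0.34)
  dec <- decompose_alignment_terms(vp$x, vp$v, vp$dvdx, p, c_prof = cprof)
  i <- 2:(nrow(dec) - 1)
  total <- with(dec, compression + advection + diffusion + active)
  expect_lt(max(abs(total[i] - dec$Q[i])), 1e-8)
  p0 <- cyto_truth(lambda_tau = 0)
  dec0 <- decompose_alignment_terms(vp$x, vp$v, vp$dvdx, p0, c_prof = cprof)
  expect_true(all(dec0$active == 0))
})
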