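# PIV, velocity profiles, compression rates, onset timing, stationarity,
# intensity profiles.

test_that("PIV recovers zero and uniform integer shifts to subpixel accuracy", {
  img <- generate_filament_image(meshwork_params(n_filaments = 120,
                                                 bias_B = 0, seed = 11))
  m0 <- piv(img, img, dt = 2, pixel_size = 0.1)
  expect_lt(max(abs(c(m0$vx, m0$vy))), 1e-9)
  shifted <- cbind(matrix(0, 256, 3), img[, 1:253])
  m3 <- piv(img, shifted, dt = 2, pixel_size = 0.1)
  dx_px <- m3$vx * (2 / 60) / 0.1
  expect_lt(max(abs(dx_px - 3)), 0.1)
  expect_error(piv(img[1:16, 1:16], img[1:16, 1:16], window_px = 32,
                   dt = 2, pixel_size = 0.1),
               "window larger")
})

test_that("PIV recovers a smooth compressive flow field to < 0.2 px RMS", {
  img <- generate_filament_image(meshwork_params(n_filaments = 120,
                                                 bias_B = 0, seed = 11))
  vp <- generate_flow_profile(flow_profile_spec("gaussian_bump", -5,
                                                center = 0, width = 5,
                                                grid = seq(-13, 13, 0.5)))
  dt_min <- 2 / 60
  adv <- advect_image(img, vp, dt = dt_min, pixel_size = 0.1)
  m <- piv(img, adv, dt = 2, pixel_size = 0.1)
  vtrue <- approx(vp$x, vp$v, xout = m$x_um, rule = 2)$y
  err_px <- (m$vx - vtrue) * dt_min / 0.1
  inner <- abs(m$x_um) < 10 & abs(m$y_um) < 10
  expect_lt(sqrt(mean(err_px[inner]^2)), 0.2)
})

test_that("velocity profiles average only valid vectors and flag gaps", {
  map <- data.frame(x_px = rep(c(10, 20), each = 4),
                    y_px = rep(1:4, 2),
                    x_um = rep(c(-1, 1), each = 4), y_um = rep(1:4, 2),
                    vx = c(-5, -5, -5, 99, 1, 2, 3, 4),
                    vy = 0, quality = 1,
                    valid = c(TRUE, TRUE, TRUE, FALSE, rep(FALSE, 4)),
                    replaced = FALSE)
  class(map) <- c("velocity_map", "data.frame")
  vp <- velocity_profile(map)
  expect_equal(vp$v[vp$x == -1], -5)          # invalid vector excluded
  expect_true(is.na(vp$v[vp$x == 1]))         # all-invalid column missing
  # band averaging of noisy vectors suppresses noise ~ sqrt(n)
  set.seed(21)
  nx <- 30; ny <- 16
  noisy <- data.frame(x_px = rep(seq_len(nx), each = ny),
                      y_px = rep(seq_len(ny), nx),
                      x_um = rep(seq_len(nx), each = ny),
                      y_um = rep(seq_len(ny), nx),
                      vx = rnorm(nx * ny), vy = 0, quality = 1,
                      valid = TRUE, replaced = FALSE)
  class(noisy) <- c("velocity_map", "data.frame")
  sd_band <- sd(velocity_profile(noisy)$v)
  expect_lt(sd_band, 1 / sqrt(ny) * 1.6)
})

test_that("compression rate recovers analytic gradients at 2nd order", {
  # constant v -> zero rate; linear v -> constant rate 0.4 / min
  x <- seq(-15, 15, by = 0.5)
  cr0 <- compression_rate(data.frame(x = x, v = rep(-3, length(x))),
                          smooth_sigma = 0)
  expect_lt(max(abs(cr0$rate)), 1e-12)
  crl <- compression_rate(data.frame(x = x, v = -0.4 * x), smooth_sigma = 0)
  expect_equal(crl$rate, rep(0.4, nrow(crl)), tolerance = 1e-10)
  # 2nd-order convergence on a smooth nonlinear profile
  errs <- vapply(c(0.5, 0.25, 0.125), function(h) {
    g <- seq(-15, 15, by = h)
    vp <- generate_flow_profile(flow_profile_spec("gaussian_bump", -5,
                                                  center = 0, width = 4,
                                                  grid = g))
    cr <- compression_rate(vp, smooth_sigma = 0)
    truth <- -vp$dvdx[match(cr$x, vp$x)]
    max(abs(cr$rate - truth))
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 3)   # ~4x per halving
  expect_gt(errs[2] / errs[3], 3)
  # noisy linear profile with smoothing: slope within 10% in the interior
  set.seed(2)
  vn <- -0.4 * x + rnorm(length(x), sd = 0.1)
  crn <- compression_rate(data.frame(x = x, v = vn), smooth_sigma = 2)
  interior <- abs(crn$x) <= 10
  expect_lt(abs(mean(crn$rate[interior]) / 0.4 - 1), 0.1)
  expect_error(compression_rate(data.frame(x = x[1:3], v = vn[1:3])),
               "too short")
})

test_that("erf onset fit recovers t0 and is translation-equivariant", {
  t <- seq(0, 8, by = 0.25)
  make_v <- function(t0, seed)
    2 + 3 * pracma::erf((t - t0) / 1.2) +
      with(list(s = seed), {set.seed(s); rnorm(length(t), sd = 0.15)})
  errs <- vapply(1:5, function(s) {
    abs(fit_onset_time(t, make_v(2.0, s))$t0 - 2.0)
  }, numeric(1))
  expect_lt(max(errs), 0.1)
  # time-shift equivariance
  set.seed(6); noise <- rnorm(length(t), sd = 0.1)
  v0 <- 2 + 3 * pracma::erf((t - 2) / 1.2) + noise
  f0 <- fit_onset_time(t, v0)
  f1 <- fit_onset_time(t + 1.5, v0)
  expect_equal(f1$t0 - f0$t0, 1.5, tolerance = 1e-6)
  # scale invariance of t0 in v
  f2 <- fit_onset_time(t, 10 * v0)
  expect_equal(f2$t0, f0$t0, tolerance = 1e-6)
  expect_error(fit_onset_time(t, rep(2, length(t))), "constant")
  expect_error(fit_onset_time(t[1:5], v0[1:5]), "at least 8")
})

test_that("stationary window detection finds plateaus and rejects ramps", {
  tt <- seq(0, 10, by = 0.1)
  # steep rise (1 min), plateau at 5 (t = 1.1 .. 7.0), steep fall
  plateau <- c(seq(0, 5, length.out = 11), rep(5, 60),
               seq(5, 0, length.out = 30))
  w <- detect_stationary_window(tt, plateau, rel_tol = 0.1)
  expect_lt(abs(w$t_start - 1.0), 0.3)
  expect_lt(abs(w$t_end - 7.0), 0.5)
  # a ramp whose 10% band spans less than the minimum duration must fail
  expect_error(detect_stationary_window(seq(0, 2, by = 0.1),
                                        seq(0, 10, length.out = 21),
                                        rel_tol = 0.1),
               "no stationary window")
  # plateau + small noise: recovered within a few frames of the truth
  set.seed(31)
  noisy <- plateau * (1 + rnorm(101, sd = 0.02))
  wn <- detect_stationary_window(tt, noisy, rel_tol = 0.1)
  expect_lt(abs(wn$t_start - 1.0), 0.4)
  expect_lt(abs(wn$t_end - 7.0), 0.7)
})

test_that("intensity profiles are band means with optional edge background", {
  img <- matrix(7, 64, 64)
  pr <- intensity_profile(img)
  expect_true(all(pr$intensity == 7))
  # Gaussian myosin-like band: peak position recovered within 1 px
  x_px <- seq_len(128)
  band <- outer(rep(1, 64), exp(-(x_px - 80)^2 / (2 * 9)))
  prb <- intensity_profile(band, pixel_size = 0.1)
  expect_lt(abs(prb$x[which.max(prb$intensity)] - (80 - 64.5) * 0.1), 0.1)
  # identical grids for two channels of the same geometry
  pr2 <- intensity_profile(band * 3 + 1, pixel_size = 0.1)
  expect_identical(prb$x, pr2$x)
  # edge background subtraction removes a constant offset
  proff <- intensity_profile(band + 2, pixel_size = 0.1, background = "edge")
  expect_lt(abs(min(proff$intensity)), 0.05)
  expect_error(intensity_profile(band, y_band = c(50, 60)), "empty")
})
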