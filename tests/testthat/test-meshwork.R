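# Synthetic meshwork generation, image advection and flow profile synthesis.

test_that("meshwork generation is deterministic and validates parameters", {
  a <- generate_filament_image(meshwork_params(n_filaments = 40, seed = 7))
  b <- generate_filament_image(meshwork_params(n_filaments = 40, seed = 7))
  expect_identical(a, b)
  cc <- generate_filament_image(meshwork_params(n_filaments = 40, seed = 8))
  expect_false(identical(a, cc))
  expect_error(meshwork_params(snr = 0), "snr")
  expect_error(meshwork_params(snr = -2), "snr")
  expect_error(meshwork_params(n_filaments = 0), "n_filaments")
  expect_error(meshwork_params(image_size = c(0, 64)), "image_size")
  expect_error(meshwork_params(bias_B = -1), "bias_B")
})

test_that("generation metadata travels with the image", {
  p <- meshwork_params(n_filaments = 60, bias_B = 1, snr = 5, seed = 2)
  img <- generate_filament_image(p)
  got <- attr(img, "params")
  expect_identical(got$n_filaments, 60L)
  expect_identical(got$snr, 5)
  expect_identical(got$seed, 2L)
})

test_that("advection: identity at v = 0 and exact integer pixel shifts", {
  img <- generate_filament_image(meshwork_params(n_filaments = 50, seed = 3,
                                                 image_size = c(128, 128)))
  x <- seq(-10, 10, by = 0.5)
  still <- advect_image(img, data.frame(x = x, v = rep(0, length(x))),
                        dt = 1, pixel_size = 0.1)
  expect_equal(matrix(still, 128, 128), matrix(img, 128, 128),
               tolerance = 1e-12)
  # uniform v with v*dt = 3 px shifts the image exactly 3 px
  vshift <- data.frame(x = x, v = rep(3 * 0.1, length(x)))  # 3 px per min
  sh <- advect_image(img, vshift, dt = 1, pixel_size = 0.1)
  expect_equal(sh[, 4:128], matrix(img, 128, 128)[, 1:125], tolerance = 1e-12)
  # displacement larger than the frame errors out
  vbig <- data.frame(x = x, v = rep(200, length(x)))
  expect_error(advect_image(img, vbig, dt = 1, pixel_size = 0.1),
               "exceeds image")
})

test_that("advection displacement matches v(x) * dt for a linear flow", {
  # dense interpolation oracle: track the shift of a narrow Gaussian spot
  px <- 0.1; W <- 256
  x_um <- (seq_len(W) - (W + 1) / 2) * px
  vgrid <- seq(-15, 15, by = 0.5)
  vprof <- data.frame(x = vgrid, v = -0.3 * vgrid)  # linear, slope -0.3/min
  dt <- 0.02
  for (x0 in c(-8, -2, 5)) {
    spot <- outer(rep(1, 64), exp(-(x_um - x0)^2 / (2 * 0.5^2)))
    adv <- advect_image(spot, vprof, dt = dt, pixel_size = px)
    # centroid displacement in px
    w0 <- colSums(spot); w1 <- colSums(adv)
    c0 <- sum(w0 * seq_len(W)) / sum(w0)
    c1 <- sum(w1 * seq_len(W)) / sum(w1)
    expected_px <- (-0.3 * x0) * dt / px
    expect_lt(abs((c1 - c0) - expected_px), 0.05)
  }
})

test_that("flow profile shapes, analytic derivatives and error checks", {
  g <- seq(-15, 15, by = 0.25)
  vp <- generate_flow_profile(flow_profile_spec("gaussian_bump", -5,
                                                center = 0, width = 5,
                                                grid = g))
  expect_equal(min(vp$v), -5, tolerance = 1e-12)
  expect_equal(vp$x[which.min(vp$v)], 0)
  # analytic derivative integrates back to v (trapezoid oracle)
  for (shape in c("gaussian_bump", "tanh_front", "linear")) {
    vp2 <- generate_flow_profile(flow_profile_spec(shape, -4, center = 2,
                                                   width = 3, grid = g))
    vrec <- vp2$v[1] + c(0, cumsum((vp2$dvdx[-1] + vp2$dvdx[-nrow(vp2)]) / 2 *
                                     diff(vp2$x)))
    expect_lt(max(abs(vrec - vp2$v)), 1e-3 * max(abs(vp2$v)))
  }
  lin <- generate_flow_profile(flow_profile_spec("linear", -0.4 * 10,
                                                 center = 0, width = 10,
                                                 grid = g))
  expect_equal(unique(round(lin$dvdx, 12)), -0.4)
  expect_error(flow_profile_spec("gaussian_bump", -5, width = 0), "width")
})

test_that("synthetic embryo datasets honour noise level, truth and seed", {
  p <- cyto_truth()
  clean <- generate_embryo_dataset(p, cyto_flow(), noise_sigma_Q = 0,
                                   seed = 5)[[1]]
  Qsolver <- as.numeric(solve_steady_Q(clean$x, clean$v, clean$dvdx, p))
  expect_identical(clean$Q, Qsolver)
  expect_identical(clean$truth, p)
  # dvdx equals the numerical derivative of v within discretisation error
  num <- diff(clean$v) / diff(clean$x)
  mid <- (clean$dvdx[-1] + clean$dvdx[-length(clean$dvdx)]) / 2
  expect_lt(max(abs(num - mid)), 0.01)
  sets <- generate_embryo_dataset(p, cyto_flow(), noise_sigma_Q = 0.02,
                                  n_embryos = 10, seed = 5)
  Qmat <- sapply(sets, `[[`, "Q")
  sds <- apply(Qmat - Qsolver, 1, sd)
  expect_gt(mean(sds), 0.015)   # chi-square band around sigma = 0.02
  expect_lt(mean(sds), 0.025)
  again <- generate_embryo_dataset(p, cyto_flow(), noise_sigma_Q = 0.02,
                                   n_embryos = 10, seed = 5)
  expect_identical(sapply(again, `[[`, "Q"), Qmat)
})

test_that("embryo datasets round-trip through CSV with truth sidecar", {
  tmp <- tempfile(fileext = ".csv")
  ds <- generate_embryo_dataset(cyto_truth(lambda_tau = 0.34), cyto_flow(),
                                myosin = myosin_band(), seed = 2)[[1]]
  write_embryo_dataset(ds, tmp)
  back <- read_embryo_dataset(tmp)
  expect_equal(back$Q, ds$Q, tolerance = 1e-12)
  expect_equal(back$c_prof, ds$c_prof, tolerance = 1e-12)
  expect_equal(back$truth$lambda_tau, 0.34)
  unlink(c(tmp, paste0(tmp, ".truth.json")))
})
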