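# Shared fixtures: the two study conditions used throughout, and a cache so
# meshwork images are generated once per test run.

# Cytokinesis-like flow: Gaussian-bump anterior-directed flow whose
# compression peak (~0.7 / min) sits at the embryo centre.
cyto_flow <- function(grid = seq(-15, 15, by = 0.5))
  flow_profile_spec("gaussian_bump", peak_velocity = -5.77, center = 5,
                    width = 5, grid = grid)

# Pseudocleavage-like weak flow: |v| <= 1 um/min front with a central
# compression peak of ~0.4 / min.
weak_flow <- function(grid = seq(-15, 15, by = 0.5))
  flow_profile_spec("tanh_front", peak_velocity = -1, center = 0,
                    width = 1.25, grid = grid)

cyto_truth <- function(lambda_tau = 0)
  gel_parameters(tau = 2.34, beta_tau = 0.654, ell = 1.69,
                 lambda_tau = lambda_tau, C1 = 0.05, C2 = 0.05)

pc_truth <- function()
  gel_parameters(tau = 0.2, beta_tau = 0.6, ell = 4.7, C1 = 0.05, C2 = 0.05)

myosin_band <- function() list(baseline = 1, amplitude = 2, center = 0, width = 3)

# Memoised meshwork analysis: mean nematic order of a generated image.
.mesh_cache <- new.env(parent = emptyenv())
mesh_mean_Q <- function(n_filaments = 100, bias_B = 1, snr = 10, seed = 1) {
  key <- paste(n_filaments, bias_B, snr, seed, sep = "_")
  if (!is.null(.mesh_cache[[key]])) return(.mesh_cache[[key]])
  img <- generate_filament_image(meshwork_params(
    n_filaments = n_filaments, bias_B = bias_B, snr = snr, seed = seed))
  q <- mean(-compute_nematic_field(img)$Qxx)
  .mesh_cache[[key]] <- q
  q
}

mesh_mean_Q_avg <- function(seeds = 1:3, ...)
  mean(vapply(seeds, function(s) mesh_mean_Q(seed = s, ...), numeric(1)))

# Oriented test pattern: parallel sinusoidal stripes at angle theta from
# the x axis (filaments run along theta; wavevector is perpendicular).
stripe_image <- function(theta, n = 128, period = 8) {
  k <- 2 * pi / period
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  sin(k * (-sin(theta) * xs + cos(theta) * ys))
}
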