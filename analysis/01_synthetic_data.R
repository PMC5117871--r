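#!/usr/bin/env Rscript
# Step 1 — synthetic study data.
#
# Generates the two kinds of ground-truth data everything downstream runs
# on: (a) filament meshwork images with a controllable vertical orientation
# bias B, and (b) embryo profile datasets whose nematic order profile is
# the steady-state solution of the gel model for a cytokinesis-like flow
# (compression peak ~0.7/min) and a pseudocleavage-like weak flow
# (|v| <= 1 um/min, peak ~0.4/min).
#
# Outputs: results/embryo_*.csv (+ .truth.json sidecars).

library(cortexflow)
dir.create("results", showWarnings = FALSE)

cyto_flow <- flow_profile_spec("gaussian_bump", peak_velocity = -5.77,
                               center = 5, width = 5,
                               grid = seq(-15, 15, by = 0.5))
weak_flow <- flow_profile_spec("tanh_front", peak_velocity = -1, center = 0,
                               width = 1.25, grid = seq(-15, 15, by = 0.5))

cyto_gel <- gel_parameters(tau = 2.34, beta_tau = 0.654, ell = 1.69,
                           lambda_tau = 0.34, C1 = 0.05, C2 = 0.05)
pc_gel <- gel_parameters(tau = 0.2, beta_tau = 0.6, ell = 4.7,
                         C1 = 0.05, C2 = 0.05)
myo <- list(baseline = 1, amplitude = 2, center = 0, width = 3)

cyto_sets <- generate_embryo_dataset(cyto_gel, cyto_flow, myosin = myo,
                                     noise_sigma_Q = 0.02, n_embryos = 12,
                                     seed = 101)
pc_sets <- generate_embryo_dataset(pc_gel, weak_flow,
                                   noise_sigma_Q = 0.02, n_embryos = 10,
                                   seed = 202)
write_embryo_dataset(average_embryo_datasets(cyto_sets),
                     "results/embryo_cytokinesis_mean.csv")
write_embryo_dataset(average_embryo_datasets(pc_sets),
                     "results/embryo_pseudocleavage_mean.csv")

cat("Cytokinesis-like condition: N =", length(cyto_sets),
    "embryos, peak compression",
    round(max(-cyto_sets[[1]]$dvdx), 2), "/min\n")
cat("Pseudocleavage-like condition: N =", length(pc_sets),
    "embryos, peak compression",
    round(max(-pc_sets[[1]]$dvdx), 2), "/min, max |v| =",
    round(max(abs(pc_sets[[1]]$v)), 2), "um/min\n")
cat("Profiles written to results/embryo_*.csv\n")
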