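#!/usr/bin/env Rscript
# Step 2 — nematic order quantification of synthetic meshworks.
#
# Measures the mean scalar order parameter Q = -<Qxx> of generated
# filament networks as a function of the orientation bias B, the filament
# density, and the image signal-to-noise ratio. Expectations: Q ~ 0 at
# B = 0, monotone growth with B that saturates (only the initial growth
# direction is biased), near-independence of density, degradation at low
# SNR.
#
# Output: results/nematic_bias_response.csv

library(cortexflow)
dir.create("results", showWarnings = FALSE)

mean_Q <- function(B = 1, n = 100, snr = 10, seeds = 1:3) {
  mean(vapply(seeds, function(s) {
    img <- generate_filament_image(meshwork_params(
      n_filaments = n, bias_B = B, snr = snr, seed = s))
    mean(-compute_nematic_field(img)$Qxx)
  }, numeric(1)))
}

bias <- data.frame(B = c(0, 0.25, 0.5, 1, 2, 4, 8))
bias$mean_Q <- vapply(bias$B, function(b) mean_Q(B = b), numeric(1))

dens <- data.frame(n_filaments = c(60, 90, 120))
dens$mean_Q <- vapply(dens$n_filaments, function(n) mean_Q(n = n), numeric(1))

snrs <- data.frame(snr = c(1, 2, 5, 10, 20))
snrs$mean_Q <- vapply(snrs$snr, function(s) mean_Q(snr = s), numeric(1))

out <- rbind(
  data.frame(sweep = "bias", value = bias$B, mean_Q = bias$mean_Q),
  data.frame(sweep = "density", value = dens$n_filaments, mean_Q = dens$mean_Q),
  data.frame(sweep = "snr", value = snrs$snr, mean_Q = snrs$mean_Q))
write.csv(out, "results/nematic_bias_response.csv", row.names = FALSE)

cat("Mean Q vs bias B:\n"); print(bias, row.names = FALSE)
cat(sprintf("Isotropy at B = 0: |Q| = %.3f (< 0.05)\n", abs(bias$mean_Q[1])))
cat(sprintf("Density robustness (60 vs 120 filaments): %.1f%% relative change\n",
            100 * abs(dens$mean_Q[1] - dens$mean_Q[3]) / max(dens$mean_Q)))
cat("Mean Q vs SNR:\n"); print(snrs, row.names = FALSE)
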