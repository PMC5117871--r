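#!/usr/bin/env Rscript
# Step 5 — spatial correlations and compression-to-alignment delays.
#
# Cross-correlates compression rate, nematic order and ingression profiles
# within the central 30-um region, localises the correlation peaks by
# Gaussian fitting, and converts the stationary peak offsets into temporal
# delays using the mean central flow speed (x in [-10, 0] um).
#
# Output: results/correlation_delays.csv

library(cortexflow)
dir.create("results", showWarnings = FALSE)
if (!file.exists("results/embryo_cytokinesis_mean.csv"))
  stop("run analysis/01_synthetic_data.R first")

cyto <- read_embryo_dataset("results/embryo_cytokinesis_mean.csv")
x <- cyto$x
comp <- -cyto$dvdx
Q <- cyto$Q
# synthetic ingression downstream of the alignment peak
u <- predict_ingression(cyto$c_prof, cyto$dvdx, Q, x, p3 = 0.8,
                        global_scale = 2.5)$u

v_bar <- mean(cyto$v[x >= -10 & x <= 0])
pairs <- list(compression_alignment = list(comp, Q),
              compression_ingression = list(comp, u),
              alignment_ingression = list(Q, u))
rows <- lapply(names(pairs), function(nm) {
  p <- pairs[[nm]]
  cc <- cross_correlate(p[[1]], p[[2]], x)
  cc <- cc[abs(cc$lag) <= 8, ]     # peaks of interest lie within a few um
  pk <- gaussian_peak_offset(cc)
  # downstream (along-flow) projection of the offset: anterior-directed
  # flow means the lagging field sits at more negative x
  dl <- offset_to_delay(pk$offset * sign(v_bar), v_bar, offset_se = pk$se)
  data.frame(pair = nm, peak_offset_um = pk$offset,
             offset_se_um = pk$se, v_mean_um_per_min = v_bar,
             delay_min = dl$delay, delay_sd_min = dl$delay_sd)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/correlation_delays.csv", row.names = FALSE)

print(tab, row.names = FALSE, digits = 3)
cat(sprintf("\nMean central flow speed: %.2f um/min\n", abs(v_bar)))
cat("The alignment peak sits anterior (downstream) of the compression peak,\n")
cat("as advection of nematic order by the flow predicts; dividing by the\n")
cat("central flow speed gives a positive compression-to-alignment delay of\n")
cat("the order of the relaxation time tau. The synthetic ingression profile\n")
cat("is generated instantaneously from the tension profiles, so its offsets\n")
cat("reflect the model's spatial structure rather than a causal time lag.\n")
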