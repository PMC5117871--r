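#!/usr/bin/env Rscript
# Step 6 — ingression prediction from anisotropic active tension.
#
# Predicts the outer ingression profile from myosin, flow and nematic
# order with one shared scale parameter fitted simultaneously to the
# pseudocleavage-like and cytokinesis-like datasets, and compares the
# anisotropic model with the isotropic (p3 = 0) control.
#
# Output: results/ingression_fit.csv, results/ingression_profiles.csv

library(cortexflow)
dir.create("results", showWarnings = FALSE)
if (!file.exists("results/embryo_cytokinesis_mean.csv"))
  stop("run analysis/01_synthetic_data.R first")

cyto <- read_embryo_dataset("results/embryo_cytokinesis_mean.csv")
pc <- read_embryo_dataset("results/embryo_pseudocleavage_mean.csv")
pc$c_prof <- rep(1, length(pc$x))   # no myosin band during pseudocleavage

# ground-truth ingression generated by the anisotropic model itself
p3_true <- 0.8; scale_true <- 2.5
mk <- function(d) {
  d$u <- predict_ingression(d$c_prof, d$dvdx, d$Q, d$x, p3 = p3_true,
                            global_scale = scale_true)$u
  # measurement noise on the contour, clipped at the eggshell
  set.seed(9)
  d$u <- pmax(d$u + rnorm(length(d$u), sd = 0.02), 0)
  d
}
ds <- list(pseudocleavage = mk(pc), cytokinesis = mk(cyto))

fit <- fit_ingression_parameter(ds, p3_mode = "fit")
tab <- data.frame(model = c("anisotropic", "isotropic (p3 = 0)"),
                  global_scale = c(fit$global_scale, fit$scale_isotropic),
                  p3 = c(fit$p3, 0),
                  rss = c(fit$rss, fit$rss_isotropic))
write.csv(tab, "results/ingression_fit.csv", row.names = FALSE)

profiles <- do.call(rbind, lapply(names(ds), function(nm)
  data.frame(stage = nm, x = ds[[nm]]$x, u_measured = ds[[nm]]$u,
             u_anisotropic = fit$predicted[[nm]]$u,
             u_isotropic = fit$predicted_isotropic[[nm]]$u)))
write.csv(profiles, "results/ingression_profiles.csv", row.names = FALSE)

print(tab, row.names = FALSE, digits = 4)
cat(sprintf("\nRecovered scale %.3f (truth %.1f), p3 %.3f (truth %.1f)\n",
            fit$global_scale, scale_true, fit$p3, p3_true))
cat(sprintf("Anisotropic rss / isotropic rss = %.3f: the isotropic control\ncannot reproduce the equatorial ingression peak.\n",
            fit$rss / fit$rss_isotropic))
cat("Note: p3 trades off against the shared scale when the myosin band and\n")
cat("the alignment band overlap spatially, so under noise p3 is less well\n")
cat("constrained than the scale (exact in the noiseless round-trip tests).\n")
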