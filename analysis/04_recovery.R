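#!/usr/bin/env Rscript
# Step 4: does the analysis recover an injected extraction artifact?
#
# Sweeps the artifact fraction f, runs the full pipeline (simulate ->
# measure -> deltas -> balance) noiselessly to get the injected excess
# (2 f [NO2-] at day 7), then over noisy seeds to quantify the spread of the
# recovered excess and the detection rate of the plain sign verdict at the
# study's noise level (0.08 mM N, 0.37 mM Fe, 3 replicates).

suppressPackageStartupMessages(library(ndfo))
dir.create("results", showWarnings = FALSE)

traj <- simulate_ndfo(t_grid = seq(0, 10, by = 0.5))
zero_sd <- c(Fe2 = 0, FeTot = 0, NO3 = 0, NO2 = 0)
n_seeds <- 50
sd_known <- sqrt(2 * (0.37^2 + 25 * 0.08^2 + 9 * 0.08^2) / 3)

rows <- lapply(c(0, 0.1, 0.25, 0.5, 1), function(f) {
  tab0 <- measure_assay(traj, f = f, noise_sd = zero_sd, n_replicates = 1, seed = 1)
  injected <- balance_report(compute_deltas(tab0, 0, 7))$excess
  exc <- vapply(seq_len(n_seeds), function(s) {
    tab <- measure_assay(traj, f = f, n_replicates = 3, seed = s)
    balance_report(compute_deltas(tab, 0, 7))$excess
  }, 0)
  data.frame(f = f, injected_excess_mM = injected,
             mean_recovered_mM = mean(exc), sd_recovered_mM = sd(exc),
             detection_rate = mean(exc > 0),
             frac_within_3sd = mean(abs(exc - injected) <= 3 * sd_known))
})
summary_tab <- do.call(rbind, rows)
print(summary_tab, digits = 3)
cat(sprintf("\nmeasurement-model SD of the mean excess (3 replicates): %.3f mM\n", sd_known))
cat("Note: at this noise level the plain sign verdict has limited per-run power\n")
cat("for small f; the excess estimate itself is unbiased up to the zero-truncation\n")
cat("of blank nitrite readings (~0.1 mM shrinkage).\n")

utils::write.csv(summary_tab, "results/recovery_summary.csv", row.names = FALSE)
cat("wrote results/recovery_summary.csv\n")
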