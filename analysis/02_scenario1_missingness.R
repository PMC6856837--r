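#!/usr/bin/env Rscript
# The core comparison: Across vs Within IPTW in Scenario 1 as the missingness
# rate grows (200 replicates per cell, n = 1000, m = 10 imputations).
# Writes results/s1_summary.csv and results/s1_replicates.csv.

suppressPackageStartupMessages(library(miprop))

cfg <- run_config(
  scenarios = "S1",
  missing_rates = c(0.10, 0.25, 0.50),
  methods = "IPTW",
  approaches = c("ACROSS", "WITHIN"),
  n = 1000L, m = 10L, n_reps = 200L,
  master_seed = 20190911L,
  output_dir = NULL,
  n_mc_calibration = 1e6)

out <- run_grid(cfg)
dir.create("results", showWarnings = FALSE)
write.csv(out$summary, "results/s1_summary.csv", row.names = FALSE)
write.csv(out$replicates, "results/s1_replicates.csv", row.names = FALSE)

s <- out$summary[order(out$summary$missing_rate, out$summary$approach), ]
print(s[, c("missing_rate", "approach", "mean_estimate", "bias", "mse",
            "mcsd", "avg_se", "coverage_pct")], digits = 3)

a50 <- s[s$missing_rate == 0.50 & s$approach == "ACROSS", ]
w50 <- s[s$missing_rate == 0.50 & s$approach == "WITHIN", ]
cat(sprintf(paste0(
  "\nAt 50%% missingness the Across approach is more biased (%.3f vs %.3f),\n",
  "its SEs understate the Monte Carlo spread (avg SE/MCSD = %.2f vs %.2f),\n",
  "and its coverage falls short (%.1f%% vs %.1f%%).\n"),
  a50$bias, w50$bias, a50$avg_se / a50$mcsd, w50$avg_se / w50$mcsd,
  a50$coverage_pct, w50$coverage_pct))
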