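#!/usr/bin/env Rscript
# Figures from the Scenario 1 comparison (run analysis/02 first):
# bias, coverage, and SE-vs-MCSD calibration against the missingness rate.
# Writes results/figures/*.pdf.

suppressPackageStartupMessages(library(miprop))

summary_path <- "results/s1_summary.csv"
if (!file.exists(summary_path)) {
  stop("run analysis/02_scenario1_missingness.R first")
}
s <- read.csv(summary_path)
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

plot_results(s, "bias", file = "results/figures/s1_bias.pdf")
plot_results(s, "coverage_pct", file = "results/figures/s1_coverage.pdf")
plot_results(s, "se", file = "results/figures/s1_se_vs_mcsd.pdf")
plot_results(s, "mse", file = "results/figures/s1_mse.pdf")
cat("wrote", length(list.files("results/figures")), "figures under results/figures\n")
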