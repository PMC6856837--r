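#!/usr/bin/env Rscript
# Complete-data baselines in Scenario 1 (1000 replicates, no missingness):
# the crude estimate quantifies the confounding, the true-model IPTW shows
# it is fully removable, and decile stratification leaves a small residual
# bias in the direction of the crude confounding.
# Writes results/complete_baselines.csv.

suppressPackageStartupMessages(library(miprop))

master <- 20190911L
set.seed(derive_seed(master, 1L, stream = 30L))
sp <- calibrate_scenario(make_scenario("S1"), n_mc = 1e6)

set.seed(derive_seed(master, 2L, stream = 30L))
n_rep <- 1000L
est <- matrix(0, n_rep, 3, dimnames = list(NULL, c("crude", "iptw", "strat")))
for (k in seq_len(n_rep)) {
  d <- simulate_complete(sp, 1000)
  ps <- fit_ps(d$X, d$z, sp$confounders)
  est[k, "crude"] <- unname(coef(lm.fit(cbind(1, d$z), d$y))[2])
  est[k, "iptw"] <- estimate_weighted(
    d$y, d$z, iptw_weights(ps$scores, d$z), "difference")$estimate
  est[k, "strat"] <- estimate_stratified(d$y, d$z, ps$scores)$estimate
}

tab <- data.frame(
  estimator = colnames(est),
  mean_estimate = colMeans(est),
  bias = colMeans(est) - 2,
  mcsd = apply(est, 2, sd),
  mc_se = apply(est, 2, sd) / sqrt(n_rep))
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/complete_baselines.csv", row.names = FALSE)
print(tab, digits = 3, row.names = FALSE)
cat(sprintf(paste0(
  "\nCrude confounding bias %.2f; IPTW removes it (bias %.3f); decile\n",
  "stratification leaves residual bias %.3f (same sign as the crude bias).\n"),
  tab$bias[tab$estimator == "crude"], tab$bias[tab$estimator == "iptw"],
  tab$bias[tab$estimator == "strat"]))
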