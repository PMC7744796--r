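#!/usr/bin/env Rscript
# Stochastic single-channel behaviour of the modulatory scheme at
# saturating cAMP: open probability and dwell times from long Gillespie
# runs, and agreement between the stochastic ensemble mean and the
# deterministic eigen-relaxation.

suppressPackageStartupMessages(library(prolineswitch))
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

wt <- build_modulatory_model()
camp <- 1000
p_sat <- unname(equilibrium_occupancy(build_rate_matrix(wt, camp)))
po_eq <- sum(p_sat[wt$conducting])
message(sprintf("Equilibrium open probability at %g uM: %.4f", camp, po_eq))

rows <- list()
for (seed in 1:3) {
  rec <- gillespie(wt, camp, duration = 200, seed = seed, p0 = p_sat)
  dw <- dwell_times(rec)
  rows[[seed]] <- data.frame(
    seed = seed, po = open_probability(rec),
    n_openings = length(dw$open_dwells),
    median_open_ms = 1000 * median(dw$open_dwells),
    mean_open_ms = 1000 * mean(dw$open_dwells),
    median_closed_ms = 1000 * median(dw$closed_dwells))
  message(sprintf(
    "seed %d: Po = %.4f over %d openings; median open dwell %.2f ms",
    seed, rows[[seed]]$po, rows[[seed]]$n_openings,
    rows[[seed]]$median_open_ms))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/tables/single_channel.csv", row.names = FALSE)
message(sprintf(
  "Mean Po across seeds: %.4f (equilibrium %.4f); openings are\nmillisecond-scale with rare long cis-branch events (mean > median).",
  mean(tab$po), po_eq))

# stochastic ensemble vs deterministic relaxation during a 0 -> 100 uM jump
p0 <- unname(equilibrium_occupancy(build_rate_matrix(wt, 0)))
times <- c(0.002, 0.005, 0.01, 0.02, 0.05)
n <- 2000
ens <- gillespie_ensemble(wt, 100, times, n_channels = n, seed = 1234,
                          p0 = p0)
det <- relax(wt, 100, p0, times)$conducting_fraction
cmp <- data.frame(time_s = times, ensemble = ens$conducting_fraction,
                  deterministic = det,
                  binomial_se = sqrt(det * (1 - det) / n))
write.csv(cmp, "results/tables/ensemble_vs_deterministic.csv",
          row.names = FALSE)
message("\nEnsemble mean vs eigen solution (0 -> 100 uM jump):")
print(round(cmp, 5))
message("Wrote single_channel.csv and ensemble_vs_deterministic.csv")
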