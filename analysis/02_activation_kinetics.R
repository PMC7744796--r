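#!/usr/bin/env Rscript
# Macroscopic activation time courses after a 0 -> 100 uM cAMP jump for
# the wild-type modulatory scheme, the isomerase-catalyzed scheme, the
# trans-only mimic and the on/off switch, with double-exponential fits of
# each curve.  This is the in-silico analogue of plotting stopped-flow
# flux rates against the delay time between cAMP mixing and the read-out.

suppressPackageStartupMessages(library(prolineswitch))
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

camp <- 100
delays <- default_delays(n = 24)        # dense grid for the figure
fit_delays <- default_delays()          # 8-point protocol grid for fits

schemes <- list(
  wild_type = build_modulatory_model(),
  with_ppiase = apply_ppiase(build_modulatory_model()),
  trans_only = build_trans_only_model(),
  on_off_switch = build_switch_model())

curves <- list(); fits <- list()
for (nm in names(schemes)) {
  tc <- simulate_activation_time_course(schemes[[nm]], camp, delays)
  curves[[nm]] <- data.frame(scheme = nm, tc)
  tc8 <- simulate_activation_time_course(schemes[[nm]], camp, fit_delays)
  f <- fit_double_exponential(tc8$delay_s, tc8$activity)
  fits[[nm]] <- data.frame(
    scheme = nm, degenerate = f$degenerate, a1 = f$a1, k1 = f$k1,
    a2 = f$a2, k2 = f$k2,
    tau_fast_s = 1 / f$k1, tau_slow_s = if (f$degenerate) NA else 1 / f$k2)
  message(sprintf(
    "%-14s activity at 12 ms: %.3f; %s",
    nm, tc8$activity[1],
    if (f$degenerate)
      sprintf("single phase, k = %.3g s^-1", f$k1)
    else
      sprintf("bi-phasic, k_fast = %.3g s^-1, k_slow = %.3g s^-1 (ratio %.0f)",
              f$k1, f$k2, f$k1 / f$k2)))
}
write.csv(do.call(rbind, curves), "results/tables/activation_time_courses.csv",
          row.names = FALSE)
write.csv(do.call(rbind, fits), "results/tables/activation_fits.csv",
          row.names = FALSE)

pdf("results/figures/activation_time_courses.pdf", width = 6, height = 4.5)
plot(NA, xlim = range(delays), ylim = c(0, 1.05), log = "x",
     xlab = "delay time (s)", ylab = "normalized activity",
     main = sprintf("Activation after 0 -> %g uM cAMP", camp))
cols <- c(wild_type = "black", with_ppiase = "darkorange",
          trans_only = "dodgerblue3", on_off_switch = "gray50")
for (nm in names(schemes))
  lines(curves[[nm]]$delay_s, curves[[nm]]$activity, col = cols[nm], lwd = 2)
legend("bottomright", names(schemes), col = cols, lwd = 2, bty = "n")
dev.off()

message("\nThe slow phase of the wild type is abolished by isomerase ",
        "catalysis and absent in the trans-only mimic; the switch scheme ",
        "keeps a (much slower) isomerization-limited phase.")
message("Wrote activation_time_courses.csv, activation_fits.csv and figure.")
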