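#!/usr/bin/env Rscript
# Fit the Monod saturation model to the replicate-averaged specific growth
# and ethanol production rates over the initial-glucose gradient, and run the
# Monte-Carlo parameter-recovery harness that quantifies how well the fit
# identifies its parameters under replicate-level noise.
# Run analysis/01_simulate.R first.

suppressPackageStartupMessages(library(fermkin))

out_dir <- "results/monod"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

recs <- read_timecourses("results/data/timecourses_substrate.csv")

rows <- list()
for (wh in c("growth", "production")) {
  pts <- rate_vs_substrate(recs, wh)
  fit <- fit_monod(pts)
  message(sprintf("%-10s rates: rate_max = %.4f, Ks = %.2f g/L, R2 = %.3f (n = %d)",
                  wh, fit$rate_max, fit$ks, fit$r2, fit$n))
  rows[[wh]] <- data.frame(which = wh, rate_max = fit$rate_max, ks = fit$ks,
                           r2 = fit$r2, sse = fit$sse, n = fit$n,
                           se_rate_max = fit$se_rate_max, se_ks = fit$se_ks,
                           converged = fit$converged)
  write.csv(pts, file.path(out_dir, sprintf("rates_%s.csv", wh)),
            row.names = FALSE)
}
write.csv(do.call(rbind, rows), file.path(out_dir, "monod_fits.csv"),
          row.names = FALSE)

# Over 50-250 g/L the growth rate is already >= 67% saturated at the lowest
# level (Ks ~ 24 g/L) and substrate inhibition flattens the top, so the
# half-saturation constant is not identifiable from that gradient (R2 near
# 0 above is expected, not a fitting failure).  A gradient reaching below Ks,
# without the inhibited branch, recovers the generating parameters:
low <- generate_study(sim_params(ki = NULL, p_crit = NULL, alpha = 1,
                                 beta = 0.02, t_end = 30, dt_out = 1,
                                 noise_cv = 0),
                      s0_grid = c(10, 20, 40, 80, 150, 250), ph_grid = 4.5,
                      salinity_grid = "seawater", replicates = 1, seed = 7)
fit_low <- fit_monod(rate_vs_substrate(low, "growth"))
message(sprintf(
  "informative gradient (10-250 g/L, no inhibition): rate_max = %.4f, Ks = %.2f g/L, R2 = %.3f",
  fit_low$rate_max, fit_low$ks, fit_low$r2))

# how trustworthy is a 5-point fit at 5% rate noise?
rec <- recovery_experiment(true_rate_max = 0.141, true_ks = 24.40,
                           s_grid = c(50, 100, 150, 200, 250),
                           noise_cv = 0.05, n_rep = 200, seed = 1)
write.csv(rec$fits, file.path(out_dir, "recovery_fits.csv"), row.names = FALSE)
write.csv(rec$summary, file.path(out_dir, "recovery_summary.csv"),
          row.names = FALSE)
message(sprintf("recovery (cv = 0.05, 200 reps): median R2 = %.3f,",
                median(rec$fits$r2)))
message(sprintf("  rate_max median bias = %+.2f%%, Ks median bias = %+.2f%%",
                100 * rec$summary$median_bias_rel[1],
                100 * rec$summary$median_bias_rel[2]))
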