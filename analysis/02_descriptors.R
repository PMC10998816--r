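#!/usr/bin/env Rscript
# Compute the per-condition kinetic descriptors (peak ethanol E_p, peak
# biomass X_m, yields Y_P/S and Y_X/S, volumetric productivity Q_p, substrate
# uptake Q_s, specific rates v_g and mu) for every simulated design axis, and
# print the base-condition summary.  Run analysis/01_simulate.R first.

suppressPackageStartupMessages(library(fermkin))

in_dir <- "results/data"
out_dir <- "results/descriptors"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

for (axis in c("substrate", "ph", "salinity")) {
  recs <- read_timecourses(file.path(in_dir, sprintf("timecourses_%s.csv", axis)))
  tab <- descriptor_table(recs)
  path <- file.path(out_dir, sprintf("descriptors_%s.csv", axis))
  write.csv(tab, path, row.names = FALSE)
  message(sprintf("%-9s axis: %d replicate rows + %d condition summaries -> %s",
                  axis, sum(tab$row_type == "replicate"),
                  sum(tab$row_type == "summary"), path))
  if (axis == "substrate") {
    base <- tab[tab$row_type == "summary" & tab$s_g0 == 150, ]
    message(sprintf(
      "  base condition (150 g/L, seawater, pH 5.5): E_p = %.2f +/- %.2f g/L, X_m = %.2f g/L,",
      base$e_p, base$e_p_sd, base$x_m))
    message(sprintf(
      "  Y_P/S = %.4f g/g, Q_p = %.3f g/(L h), v_g = %.3f g/(g h), mu = %.4f 1/h",
      base$y_ps, base$q_p, base$v_g, base$mu))
  }
}
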