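#!/usr/bin/env Rscript
# Generate the three one-factor-at-a-time designs of the simulated
# optimization study with the reference ("ze75-like") preset:
#   - initial glucose gradient 50-250 g/L at pH 5.5 in seawater medium
#   - pH gradient 3-7 (step 0.5) at 175 g/L glucose in seawater medium
#   - salinity gradient (distilled .. 4 M NaCl) at 175 g/L glucose, pH 5.5
# Three replicates per condition with 2% multiplicative measurement noise.
# Writes tidy time-course CSVs under results/data/.

suppressPackageStartupMessages(library(fermkin))

seed <- 1L
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

params <- sim_params(noise_cv = 0.02)
stress <- stress_params()

designs <- list(
  substrate = list(s0 = c(50, 75, 100, 125, 150, 175, 200, 225, 250),
                   ph = 5.5, sal = "seawater"),
  ph = list(s0 = 175, ph = seq(3, 7, by = 0.5), sal = "seawater"),
  salinity = list(s0 = 175, ph = 5.5,
                  sal = c("distilled", "half_seawater", "seawater",
                          "1", "2", "3", "4"))
)

for (ai in seq_along(designs)) {
  axis <- names(designs)[ai]
  d <- designs[[axis]]
  recs <- generate_study(params, stress, s0_grid = d$s0, ph_grid = d$ph,
                         salinity_grid = d$sal, replicates = 3L,
                         seed = derive_seed(seed, ai))
  path <- file.path(out_dir, sprintf("timecourses_%s.csv", axis))
  write_timecourses(recs, path)
  message(sprintf("%-9s axis: %3d time courses -> %s",
                  axis, length(recs), path))
}
message("done; downstream scripts read these files back with read_timecourses()")
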