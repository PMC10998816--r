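#!/usr/bin/env Rscript
# Statistical comparison layer: one-way ANOVA + Tukey HSD letter displays per
# descriptor for each design axis, and identification of the optimal
# condition (peak ethanol for the substrate and pH axes, ethanol yield for
# the salinity axis).  Run analysis/01_simulate.R and 02_descriptors.R first.

suppressPackageStartupMessages(library(fermkin))

out_dir <- "results/comparison"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
alpha <- 0.05

optimum_metric <- c(substrate = "e_p", ph = "e_p", salinity = "y_ps")
opt_rows <- list()

for (axis in names(optimum_metric)) {
  recs <- read_timecourses(sprintf("results/data/timecourses_%s.csv", axis))
  tab <- descriptor_table(recs)
  reps <- tab[tab$row_type == "replicate", ]

  # letter table for the headline metric, printed the way descriptor tables
  # are usually typeset (groups sharing a letter are not distinguishable)
  metric <- optimum_metric[[axis]]
  groups <- split(reps[[metric]], factor(reps$condition_id,
                                         levels = unique(reps$condition_id)))
  th <- tukey_hsd(groups, alpha)
  cl <- compact_letters(th)
  disp <- data.frame(condition = names(groups),
                     mean = sapply(groups, mean),
                     sd = sapply(groups, sd),
                     letters = cl[names(groups)])
  write.csv(disp, file.path(out_dir, sprintf("letters_%s_%s.csv", axis, metric)),
            row.names = FALSE)
  message(sprintf("%s axis, %s (ANOVA F = %.1f, p = %.2g):",
                  axis, metric, th$anova$f_stat, th$anova$p_value))
  o <- order(-disp$mean)
  message(paste(sprintf("  %-22s %8.4f +/- %.4f  %s", disp$condition[o],
                        disp$mean[o], disp$sd[o], disp$letters[o])[1:min(5, nrow(disp))],
                collapse = "\n"))

  opt <- find_optimum(tab, metric, alpha)
  opt_rows[[axis]] <- data.frame(axis = axis, metric = metric,
                                 best = opt$best_condition,
                                 best_mean = opt$best_mean,
                                 co_optimal = paste(opt$co_optimal,
                                                    collapse = ";"))
  message(sprintf("  optimum: %s (co-optimal: %s)\n",
                  opt$best_condition, paste(opt$co_optimal, collapse = ", ")))
}
write.csv(do.call(rbind, opt_rows), file.path(out_dir, "optima.csv"),
          row.names = FALSE)
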