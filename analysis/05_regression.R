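#!/usr/bin/env Rscript

# Stage 5: the statistical layer — join the measured tables, screen each
# variable for normality (Lilliefors-corrected KS), summarize as
# mean +/- SD, and fit the two families of pairwise regressions (fat
# fraction vs. strength/density/microstructure; normalized failure load
# vs. the rest) with 1000-sample bootstrap validation of each slope.

suppressPackageStartupMessages(library(marrowmech))

study <- "results/study"
pdff <- read.csv(file.path(study, "pdff_measured.csv"))
morpho <- read.csv(file.path(study, "morphometry_measured.csv"))
fl <- read.csv(file.path(study, "failure_load_measured.csv"))

cohort <- Reduce(function(a, b) merge(a, b, by = "specimen_id"),
                 list(pdff[, c("specimen_id", "fat_fraction")],
                      morpho[, c("specimen_id", "bmd", "bv_tv", "tbn", "fd",
                                 "mean_area", "min_area")],
                      fl[, c("specimen_id", "fl", "norm_fl")]))
write.csv(cohort, file.path(study, "cohort_measured.csv"), row.names = FALSE)

summary_tbl <- summarize_cohort(cohort)
write.csv(summary_tbl, file.path(study, "summary.csv"), row.names = FALSE)
cat("summary (mean +/- SD):\n")
for (i in seq_len(nrow(summary_tbl))) {
  cat(sprintf("  %-12s %10.2f +/- %.2f\n", summary_tbl$variable[i],
              summary_tbl$mean[i], summary_tbl$sd[i]))
}

vars <- c("fat_fraction", "bmd", "bv_tv", "tbn", "fd", "norm_fl")
norm_tbl <- data.frame(
  variable = vars,
  p = vapply(vars, function(v) ks_normality(cohort[[v]])$p, numeric(1)))
write.csv(norm_tbl, file.path(study, "normality.csv"), row.names = FALSE)
cat(sprintf("normality screen: smallest Lilliefors p = %.3f (%s)\n",
            min(norm_tbl$p), norm_tbl$variable[which.min(norm_tbl$p)]))

reg <- regression_table(cohort, seed = 20L, n_boot = 1000)
write.csv(reg, file.path(study, "regressions.csv"), row.names = FALSE)
cat("pairwise regressions (r, p, bootstrap p):\n")
for (i in seq_len(nrow(reg))) {
  cat(sprintf("  %-12s ~ %-12s r = %+.2f  p = %.3f  p_boot = %.3f\n",
              reg$y[i], reg$x[i], reg$r[i], reg$p[i], reg$p_boot[i]))
}
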