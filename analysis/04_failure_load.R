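#!/usr/bin/env Rscript

# Stage 4: extract each specimen's failure load — the first peak of its
# load-displacement curve followed by a drop of more than 10% — and
# normalize by the minimum cross-sectional area measured in stage 3.

suppressPackageStartupMessages(library(marrowmech))

study <- "results/study"
morpho <- read.csv(file.path(study, "morphometry_measured.csv"))

rows <- lapply(seq_len(nrow(morpho)), function(i) {
  id <- morpho$specimen_id[i]
  curve <- read_load_curve(file.path(study, "curves", paste0(id, ".csv")))
  det <- detect_failure_load(curve)
  stopifnot(det$detected)
  data.frame(specimen_id = id,
             fl = det$failure_load,
             drop_observed = det$drop_observed,
             norm_fl = normalize_fl(det$failure_load, morpho$min_area[i]))
})
fl <- do.call(rbind, rows)
write.csv(fl, file.path(study, "failure_load_measured.csv"),
          row.names = FALSE)
cat(sprintf(
  "failure load for %d specimens: FL %.0f +/- %.0f N, normalized %.0f +/- %.0f N/cm^2\n",
  nrow(fl), mean(fl$fl), sd(fl$fl), mean(fl$norm_fl), sd(fl$norm_fl)))
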