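#!/usr/bin/env Rscript

# Stage 1: simulate the study's raw material for a ten-specimen cohort —
# the specimen table with its correlated variables, one four-echo spectrum
# set per specimen, one trabecular CT volume with calibration phantom per
# specimen, and one load-displacement curve per specimen. Everything
# downstream (02-05) reads only what this script writes under
# results/study/.

suppressPackageStartupMessages(library(marrowmech))

study_seed <- 20L
out <- "results/study"
for (d in c(out, file.path(out, c("spectra", "volumes", "curves")))) {
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
}

cohort <- generate_cohort(cohort_sim_spec(n_specimens = 10,
                                          seed = derive_seed(study_seed, 1)))
write.csv(cohort$cohort, file.path(out, "cohort_true.csv"), row.names = FALSE)
cat("cohort: 10 specimens, fat fraction",
    sprintf("%.1f +/- %.1f %%", mean(cohort$cohort$fat_fraction),
            sd(cohort$cohort$fat_fraction)), "\n")

for (i in seq_len(nrow(cohort$cohort))) {
  row <- cohort$cohort[i, ]
  id <- row$specimen_id

  # four-echo spectra at the specimen's fat fraction, realistic SNR
  ss <- generate_spectrum(spectrum_sim_spec(
    pdff_true = min(max(row$fat_fraction / 100, 0.01), 0.99),
    snr = 50, seed = derive_seed(study_seed, 100 + i)))
  write_spectra(ss, file.path(out, "spectra", id))

  # trabecular lattice volume + phantom, lattice period set by the
  # specimen's BV/TV and bone density by its BMD
  f <- max(0.05, min(0.9, row$bv_tv / 100))
  period <- max(2L, round(1 / f))
  vol <- generate_volume(volume_sim_spec(
    shape = c(72, 72, 24),
    lattice = list(type = "plate", thickness = 0.23,
                   spacing = (period - 1) * 0.23, orientation = "x"),
    bone_density = max(210, (row$bmd - 50 * (1 - 1 / period)) * period),
    marrow_density = 50,
    seed = derive_seed(study_seed, 200 + i)))
  write_volume_nifti(vol$hu, vol$voxel_size,
                     file.path(out, "volumes", paste0(id, ".nii.gz")))
  jsonlite::write_json(
    list(phantom = vol$truth$phantom,
         lattice_region = vol$truth$lattice_region,
         bv_tv_true = vol$truth$bv_tv),
    file.path(out, "volumes", paste0(id, "_truth.json")),
    auto_unbox = TRUE, digits = NA)

  # softening load curve at the specimen's failure load
  fl_true <- max(row$fl, 100)
  curve <- generate_load_curve(fl_true, drop_fraction = 0.25,
                               seed = derive_seed(study_seed, 300 + i))
  write_load_curve(curve, file.path(out, "curves", paste0(id, ".csv")))
}
cat("wrote spectra, volumes and load curves for 10 specimens to", out, "\n")
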