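# marrowmech

Vertebral bone marrow fat, trabecular bone microstructure and bone
strength, analyzed as one chain.

Bone marrow adiposity is increasingly implicated in the pathophysiology
of osteoporosis: marrow fat fraction rises as trabecular bone density
falls, and both relate to the mechanical competence of the vertebra.
`marrowmech` implements the complete in-vitro analysis pipeline used to
study these relationships on cadaveric vertebrae, for researchers in
quantitative musculoskeletal imaging who want each stage as a tested,
reusable R function:

1. **MRS fat quantification** — multi-echo single-voxel spectra are
   phased, fitted with a constrained nine-peak Gaussian model (fat groups
   A–F, two water components, areas of E and F tied to A + B by
   triglyceride stoichiometry, three free linewidths), T2-corrected by
   mono-exponential extrapolation to TE = 0, and reduced to the
   proton-density fat fraction
   PDFF = fat / (fat + narrow water).
2. **QCT morphometry** — phantom calibration maps HU to mg/cm³ calcium
   hydroxyapatite; a centred 12 × 12 mm² ROI over the 20 most central
   slices yields BMD, BV/TV, trabecular number TbN = (BV/TV)/Tb.Th\*
   via the mean intercept length method, box-counting fractal dimension,
   and mean/minimum cross-sectional areas.
3. **Biomechanics** — the failure load is the first peak of the
   load–displacement curve followed by a drop of more than 10%,
   normalized by the minimum cross-sectional area.
4. **Statistics** — Lilliefors-corrected KS normality screening, pairwise
   linear regressions (slope B, SE, Pearson r, p), and 1000-sample case
   bootstrap validation of every slope.

Because the original specimens are not publicly available, a
synthetic-data module generates all four inputs — spectra with nine fat
resonances and two water components, trabecular lattice CT volumes with
an embedded calibration phantom, softening load curves, and correlated
specimen cohorts — with exact ground truth, so the full chain is testable
end to end.

## Worked example

Simulate a four-echo acquisition at 32% marrow fat and re-measure it:

```r
library(marrowmech)

set <- generate_spectrum(spectrum_sim_spec(pdff_true = 0.32, snr = Inf))
res <- fit_pdff(set)
c(pdff = res$pdff, t2_fat = res$t2_fat, t2_water = res$t2_water)
#>      pdff    t2_fat  t2_water
#>      0.32     80.00     25.00
```

The estimated PDFF equals the generating value (recovery is at machine
precision without noise; mean absolute error ≈ 0.005 at SNR 50), and the
fat/water T2 values (80 / 25 ms) that produced the decay are recovered —
water relaxes faster than fat, which is exactly why single-echo fat
fractions are biased and the T2 correction exists.

Morphometry on a quarter-filled plate lattice, where every quantity has a
closed form:

```r
vol <- generate_volume(volume_sim_spec(shape = c(64, 64, 32)))
mask <- vol$truth$mask
bv_tv(mask)                                   # 25  (% bone, exact)
mil_tbn(mask, vol$voxel_size, "x")$mil[["x"]] # 0.23 (mm, one plate)
mil_tbn(mask, vol$voxel_size, "x")$tbn        # 1.0869... = 0.25 / 0.23
```

The full ten-specimen study, as numbered analysis scripts (each stage
writes CSVs under `results/study/` that the next stage reads):

```sh
Rscript analysis/01_simulate.R      # cohort, spectra, volumes, curves
Rscript analysis/02_fit_spectra.R   # PDFF per specimen
Rscript analysis/03_morphometry.R   # BMD, BV/TV, TbN, FD, areas
Rscript analysis/04_failure_load.R  # FL and normalized FL
Rscript analysis/05_regression.R    # summary, normality, regressions
```

A run of that chain prints, at the end:

```
summary (mean +/- SD):
  fat_fraction      31.60 +/- 5.65
  bmd              120.20 +/- 25.10
  ...
pairwise regressions (r, p, bootstrap p):
  norm_fl      ~ fat_fraction r = -0.73  p = 0.017  p_boot = 0.006
  bmd          ~ fat_fraction r = -0.80  p = 0.005  p_boot = 0.004
  ...
  bmd          ~ norm_fl      r = +0.87  p = 0.001  p_boot = 0.002
```

i.e. the simulated study reproduces the published pattern: marrow fat
fraction correlates negatively with normalized failure load and BMD,
while normalized failure load correlates strongly and positively with
density and microstructure. `run_pipeline()` performs the same chain
in-process with a manifest for bit-exact reproducibility.

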