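---
title: "Methods: marrow fat quantification, trabecular morphometry and bone strength"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marrow fat quantification, trabecular morphometry and bone strength}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marrowmech)
```

`marrowmech` implements the analysis chain of an in-vitro vertebral study
linking bone marrow adiposity to bone strength: single-voxel MR
spectroscopy quantifies the marrow proton-density fat fraction (PDFF),
quantitative CT yields trabecular density and microstructure, destructive
compression testing yields the failure load, and pairwise linear
regression with bootstrap validation ties them together. Because the
underlying cadaveric measurements are not publicly available, the package
ships a synthetic-data module that emulates all four inputs with known
ground truth; every downstream stage is exercised against that ground
truth.

## The spectroscopic model

A marrow spectrum at 3 T contains nine triglyceride resonances (0.90,
1.30, 1.59, 2.00, 2.25, 2.77, 4.20, 5.19 and 5.31 ppm) and a water signal
at 4.7 ppm. The fit groups them as A (0.90), B (1.30 + 1.59),
C (2.00 + 2.25), D (2.77), E (4.20) and F (5.19 + 5.31), and models water
as two components — a narrow (long T2\*) and a broad (short T2\*) peak —
because the marrow water pool is not mono-exponential. All peaks are
Gaussian. Three structural constraints stabilize the fit where fat and
water overlap (E and F sit under the water resonance):

* the areas of E and F are tied to the area of A + B at fixed ratios
  derived from triglyceride stoichiometry,
* all nine fat peaks share one linewidth, and each water component has
  its own — exactly three linewidths are free,
* fat positions may move at most ±0.05 ppm, water positions ±0.50 ppm.

The constraint ratios come from a triglyceride proton model parameterized
by mean chain length `cl`, double bonds `ndb` and methylene-interrupted
double bonds `nmidb`:

```{r}
trig <- triglyceride_protons(cl = 17.4, ndb = 2.8, nmidb = 0.7)
round(c(trig$per_group, ratio_E = trig$ratio_E, ratio_F = trig$ratio_F), 3)
```

The defaults (17.4 / 2.8 / 0.7) describe a typical vertebral marrow
triglyceride; they are the implementer's choice, exposed as configuration
because published marrow compositions vary and the original constraint
values are not printed anywhere we could copy them from. Changing them
changes the constraint ratios consistently in the generator *and* the
fitter, so recovery tests remain meaningful.

### Fitting: variable projection, coarse-to-fine

Given peak positions and linewidths the model is *linear* in the six free
areas (A, B, C, D, narrow water, broad water) — E and F fold into the A
and B basis columns through the constraint ratios. `fit_peaks()` exploits
this: a bounded Levenberg–Marquardt search runs over only the 14
nonlinear parameters (11 position offsets, 3 linewidths), solving a
non-negative least-squares problem for the areas at every step. Two
details matter in practice:

* **Coarse-to-fine.** The linewidths are fitted first with positions
  pinned at their nominal shifts; all 14 parameters are then released.
  Started from wrong linewidths, the position search can park the small
  constrained 5.19 ppm peak against its ±0.05 ppm bound and stall in a
  local minimum; starting it from near-correct linewidths removes that
  failure mode.
* **Label stability.** The narrow/broad water identity is assigned
  *after* fitting by comparing fitted linewidths (smaller = narrow), so a
  label swap during optimization cannot corrupt the PDFF.

The fit window is −1 to 7.5 ppm: all model peaks live in 0–6 ppm and
points far outside carry no model signal. Defaults: fat/narrow-water
linewidth start 20 Hz, broad water 100 Hz, linewidth bounds 1–500 Hz,
cost tolerance 1e−10, spectra fitted on the phased real signal rather
than the magnitude (magnitude noise is non-Gaussian and breaks peak
additivity where peaks overlap). Zero-order phasing maximizes the
integral of the real part over 0–6 ppm, which has the closed-form
solution of the argument of the complex integral.

### T2 correction and PDFF

Peak areas are fitted per echo (TE = 12/15/20/25 ms by default; long TR
removes T1 weighting by design). `t2_correct()` then fits
`area(TE) = area0 · exp(−TE/T2)` by nonlinear least squares, once for the
*summed* fat area (the model assumes one fat T2, so summation loses
nothing and stabilizes the fit) and once for the narrow water area, with
T2 bounded in [1, 1000] ms. Exactly two echoes degrade to the flagged
two-point closed form; a non-decaying sequence pins T2 at the upper bound
and is flagged, never silently accepted. Finally

$$\mathrm{PDFF} = \frac{\text{fat area at TE}=0}
{\text{fat area at TE}=0 + \text{narrow-water area at TE}=0},$$

excluding the broad (short T2\*) water component by definition. Water
(T2 ≈ 25 ms) decays faster than fat (≈ 80 ms), so a single-echo signal
fat fraction overshoots PDFF — the test suite checks this bias
direction explicitly, which is the reason multi-echo T2 correction exists
in the chain.

```{r}
set <- generate_spectrum(spectrum_sim_spec(pdff_true = 0.32, snr = Inf))
res <- fit_pdff(set)
c(pdff = res$pdff, t2_fat = res$t2_fat, t2_water = res$t2_water)
```

## Quantitative CT morphometry

`calibrate()` regresses nominal phantom densities on measured HU (ordinary
least squares via `lm`); `apply_calibration()` maps the volume to
mg/cm³ calcium hydroxyapatite. The analysis ROI is a centred
12 × 12 mm² window over the 20 most central slices; 12 mm at 0.23 mm
pixels rounds to 52 voxels (nearest integer, ties toward the larger
window). Binarization uses a global threshold of 200 mg/cm³, *inclusive*:
a voxel exactly at the threshold is bone. The boundary semantics are a
documented choice — the threshold itself is standard, its edge behaviour
is not specified anywhere, and an inclusive rule makes the
threshold-monotonicity property exact.

* **BV/TV** is the bone voxel fraction, in percent.
* **TbN** comes from the mean intercept length: one test line per voxel
  row along each requested axis, physical (anisotropy-aware) lengths,
  `MIL = total bone length / marrow→bone transitions`. Transitions are
  counted strictly and wrap-free — a bone run that starts a line is not
  an entry. A direction with no transitions at all (lines parallel to
  plates) degrades to the mean bone length of lines containing bone,
  i.e. the full line length for solid rows; this convention is tested
  against the axis-aligned lattice fixtures where every quantity is known
  in closed form. The closure `TbN = (BV/TV)/Tb.Th*` with `Tb.Th*` the
  direction-averaged MIL is the plate-model identity of classical
  histomorphometry; it is the largest interpretive choice in this module
  and is isolated in `mil_tbn()` so an intersections-per-length variant
  could be swapped in.
* **FD** is the 2-D box-counting dimension computed per transverse slice
  and averaged: occupied-box counts N(s) for s ∈ {2, 4, …, 64} pixels,
  grid anchored at the slice origin, partial border boxes counted, least
  squares slope of log N(s) against log(1/s). Counting uses the bone mask
  itself, not its boundary; a filled plane gives exactly 2 and a
  one-pixel line exactly 1, anchoring the implementation. The 2-D choice
  matches the fact that trabecular texture FD values reported for such
  data sit in the planar range [1, 2].
* **Cross-sectional areas** are per-slice pixel counts times the in-plane
  pixel area; the mean and minimum are taken over nonempty slices.

## Failure load

`detect_failure_load()` scans local maxima of the load–displacement curve
in order. A maximum M qualifies if the minimum load after it — up to the
sample where the load first exceeds M again, or the curve end — falls
strictly below 0.9 M. "More than 10%" is read as strictly greater, so an
exactly-10% drop does not qualify; the boundary is tested. The drop
window ends when the load re-exceeds M because a subsequent drop must
belong to *that* peak, not to a later structure. The first qualifying
maximum is returned at its unsmoothed load value; an optional centred
moving average (off by default) is exposed because physical test rigs
produce jitter, and the detection is verified against a brute-force scan
of every local maximum on random piecewise-linear curves. Normalized
failure load divides by the minimum cross-sectional area (N/cm²).

## Statistics

All pairwise models are simple linear regressions computed in closed
form: slope B, its standard error, Pearson r (carrying the sign of B) and
the two-sided p from the t distribution with n − 2 degrees of freedom;
the implementation is cross-checked against `lm` and an independent
design-matrix oracle at 1e−10. Normality screening uses the
one-sample Kolmogorov–Smirnov test with Lilliefors correction
(`nortest::lillie.test`), because the null parameters are estimated from
the sample; the uncorrected variant is available via a flag for
comparability with legacy software.

`bootstrap_regression()` resamples *cases* (specimen pairs) with
replacement — matching a design where whole specimens are the sampling
unit — with a seeded RNG, 1000 replicates by default. The bootstrap SE is
the SD of replicate slopes. The bootstrap p-value is the two-sided
sign-crossing proportion `2·min(frac(B* ≤ 0), frac(B* ≥ 0))`, floored at
`2/n_boot`; a normal-approximation alternative (`B/se_boot` against the
standard normal) is provided as an option since the original analysis
does not state its bootstrap p definition. Degenerate replicates
(constant x) are redrawn and counted. No multiple-testing correction is
applied anywhere, matching the source analysis; with ten pairwise models
this is a real limitation to keep in mind when reading the p-values.

## The synthetic cohort

`generate_cohort()` draws specimens from a multivariate normal — the
study variables showed no significant departure from normality — with
means and SDs matching the published cohort (fat fraction 32 ± 5 %, BMD
121.5 ± 34.3 mg/cm³, BV/TV 38.8 ± 10.8 %, TbN 1.13 ± 0.11 mm⁻¹,
FD 1.57 ± 0.07, normalized FL 442 ± 251 N/cm², mean area 6.5 ± 1.5 cm²).
Only the correlations of fat fraction and normalized FL with the other
variables are published; the correlations *among* the density and
microstructure variables, and between the two area measures, were fixed
once at trabecular-typical values (0.70–0.85; areas 0.90) chosen to keep
the matrix positive definite (smallest eigenvalue 0.019). The minimum
cross-sectional area (5.9 ± 1.4 cm²) sits slightly below the mean area so
that `fl = norm_fl × min_area` reproduces the reported absolute failure
load scale (≈ 2580 N). The transform uses the eigendecomposition of the
correlation matrix, so positive-*semi*definite inputs and zero SDs are
handled exactly, and every generator restores the caller's RNG state.

A Gaussian model has unbounded tails: at cohort scale an occasional draw
is non-physical (a negative load roughly three SDs below the mean). The
end-to-end pipeline clamps such rows to physical floors (min area
≥ 1 cm², normalized FL ≥ 20 N/cm²) before simulating measurements;
the generator itself never modifies its draws.

### What the generators do and do not emulate

The spectrum generator produces exactly the fitted forward model
(Gaussian peaks, shared decay constants, additive complex white noise at
an SNR defined against the tallest methylene peak at the shortest echo).
Passing recovery tests therefore demonstrates that the estimation chain
is *correct and well-conditioned*, not that it is robust to
eddy-current phase distortions, J-coupling evolution, baseline roll or
lineshape departures from Gaussian — none of which are modelled. The
lattice volumes are axis-aligned plate/rod arrays with a marrow-led
phase, so MIL ground truth is closed-form; real trabecular networks are
oblique, connected and noisy, and the MDCT point-spread function is not
modelled (partial-volume blur is absent). Load curves are piecewise
linear with an exact grid point at the peak. Cohort-level tests check the
statistical layer, not biology: the generating correlation matrix *is*
the hypothesis.

## Problem sizes and reproducibility

The test suite runs spectrum fits at the full acquisition size (4096
points, 5 kHz, four echoes) where the acquisition itself is under test,
and at 1024 points in unit tests of surrounding logic; oracle
comparisons use 1000 random volumes up to 16³ voxels and 1000 random
load curves, sizes at which exhaustive brute-force recomputation stays
exact and fast. The end-to-end pipeline default is ten specimens with
72 × 72 × 24-voxel volumes — the cohort scale of the original study.

Every random stage takes an explicit integer seed; `run_pipeline()`
derives per-stage seeds from one global seed via a fixed affine-modular
map (`derive_seed()`), so single stages can be reproduced in isolation
and two runs from the same configuration are bit-identical. The pipeline
writes a JSON manifest (configuration snapshot, package version, output
checksums, timestamps) on success *and* on failure.

## Known limitations

* TbN depends on the documented plate-model closure; alternative
  closures give systematically different absolute values on the same
  mask.
* FD is resolution- and convention-dependent (mask-based counting,
  partial boxes included); comparisons across implementations need
  matching conventions.
* The spectral model assumes Gaussian lineshapes and one shared fat T2;
  marrow spectra with strong field inhomogeneity violate both.
* The cohort generator reproduces first- and second-order moments only;
  any nonlinear structure in real specimen populations is out of reach.
* At n = 10, single-study correlation estimates are wide; the
  cohort-level tests therefore check coverage of the sampling
  distribution rather than point equality.
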