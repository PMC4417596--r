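# Small, fast spectra for fitting tests; the full acquisition size is
# exercised in the acceptance suite.
quick_spec <- function(...) {
  spectrum_sim_spec(n_points = 1024, ...)
}

test_that("zero-order phasing inverts a known phase rotation", {
  ss <- generate_spectrum(quick_spec(snr = Inf))
  sp <- ss$spectra[[1]]
  rotated <- sp
  rotated$signal <- sp$signal * exp(1i * pi / 2)
  rec <- phase_spectrum(rotated)
  expect_equal(as.numeric(rec$signal), Re(sp$signal), tolerance = 1e-9)
})

test_that("phasing is idempotent on an already-real positive spectrum", {
  ss <- generate_spectrum(quick_spec(snr = Inf))
  ph <- phase_spectrum(ss$spectra[[1]])
  ph2 <- phase_spectrum(ph)
  expect_identical(as.numeric(ph2$signal), as.numeric(ph$signal))
  expect_equal(attr(ph2, "phase_applied"), 0)
})

test_that("phasing recovers the noiseless template from a random phase", {
  template <- generate_spectrum(quick_spec(snr = Inf, phase0 = 0))
  rotated <- generate_spectrum(quick_spec(snr = Inf, phase0 = 2.1))
  rec <- phase_spectrum(rotated$spectra[[1]])
  expect_equal(as.numeric(rec$signal), Re(template$spectra[[1]]$signal),
               tolerance = 1e-9)
})

test_that("phasing rejects an identically zero spectrum", {
  sp <- mrs_spectrum(seq(-2, 10, length.out = 256), complex(256), te = 12)
  expect_error(phase_spectrum(sp), "empty spectrum")
})

test_that("noiseless group areas are recovered to high relative accuracy", {
  ss <- generate_spectrum(quick_spec(pdff_true = 0.32, snr = Inf))
  fit <- fit_peaks(ss$spectra[[1]])
  truth <- ss$truth$fat_group_areas_te0 * exp(-12 / ss$truth$t2_fat)
  for (g in c("A", "B", "C", "D", "E", "F")) {
    expect_lt(abs(fit$areas[[g]] - truth[[g]]) / truth[[g]], 1e-4)
  }
  wn_truth <- ss$truth$water_narrow_area_te0 * exp(-12 / ss$truth$t2_water)
  expect_lt(abs(fit$areas[["water_narrow"]] - wn_truth) / wn_truth, 1e-4)
})

test_that("a water-free spectrum yields negligible fitted water area", {
  ss <- generate_spectrum(quick_spec(pdff_true = 1, snr = Inf))
  fit <- fit_peaks(ss$spectra[[1]])
  fat_total <- sum(fit$areas[c("A", "B", "C", "D", "E", "F")])
  expect_lt(fit$areas[["water_narrow"]] + fit$areas[["water_broad"]],
            1e-6 * fat_total)
})

test_that("a single isolated Gaussian is recovered at its analytic area", {
  # constraint ratios 0 so no E/F mass is forced by the lone peak
  field <- 3
  ppm <- seq(-2, 10, length.out = 2048)
  hz <- ppm * field * marrowmech:::GAMMA_1H_MHZ_PER_T
  fwhm <- 30
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  amp <- 5
  area_true <- amp * sigma * sqrt(2 * pi)
  # group A is the single 0.9 ppm methyl resonance, so the constrained
  # model (ratios 0) can represent a lone Gaussian there exactly
  centre <- ppm_to_hz(0.90, field)
  signal <- amp * exp(-(hz - centre)^2 / (2 * sigma^2))
  sp <- mrs_spectrum(ppm, signal, te = 12, field_strength = field)
  model <- peak_model(constraint_ratios = c(E = 0, F = 0))
  fit <- fit_peaks(sp, model)
  expect_lt(abs(fit$areas[["A"]] - area_true) / area_true, 1e-6)
})

test_that("E and F areas satisfy the constraint ratios exactly", {
  model <- peak_model()
  for (snr in c(Inf, 30)) {
    ss <- generate_spectrum(quick_spec(pdff_true = 0.32, snr = snr, seed = 5))
    fit <- fit_peaks(ss$spectra[[1]], model)
    ab <- fit$areas[["A"]] + fit$areas[["B"]]
    expect_identical(fit$areas[["E"]], model$constraint_ratios[["E"]] * ab)
    expect_identical(fit$areas[["F"]], model$constraint_ratios[["F"]] * ab)
  }
})

test_that("fitting is scale-equivariant and PDFF scale-invariant", {
  ss <- generate_spectrum(quick_spec(pdff_true = 0.4, snr = Inf))
  res1 <- fit_pdff(ss)
  scaled <- lapply(ss$spectra, function(sp) {
    sp$signal <- sp$signal * 7.3
    sp
  })
  res2 <- fit_pdff(scaled)
  expect_equal(res2$area_fat_te0, 7.3 * res1$area_fat_te0,
               tolerance = 1e-6)
  expect_equal(res2$pdff, res1$pdff, tolerance = 1e-6)
})

test_that("two-point T2 correction matches the closed form exactly", {
  mk_fit <- function(fat, wn, te) {
    structure(list(areas = c(A = fat, B = 0, C = 0, D = 0, E = 0, F = 0,
                             water_narrow = wn, water_broad = 0), te = te),
              class = "peak_fit")
  }
  fits <- list(mk_fit(exp(-12 / 50), exp(-12 / 50), 12),
               mk_fit(exp(-25 / 50), exp(-25 / 50), 25))
  res <- suppressWarnings(t2_correct(fits))
  expect_equal(res$t2_fat, 50, tolerance = 1e-12)
  expect_equal(res$area_fat_te0, 1, tolerance = 1e-12)
  expect_match(res$flags[["fat"]], "two_point")
})

test_that("four-echo noiseless T2 recovery is sub-0.5%", {
  ss <- generate_spectrum(quick_spec(pdff_true = 0.32, snr = Inf,
                                     t2_fat = 80, t2_water = 25))
  res <- fit_pdff(ss)
  expect_lt(abs(res$t2_fat - 80) / 80, 0.005)
  expect_lt(abs(res$t2_water - 25) / 25, 0.005)
})

test_that("a non-decaying area sequence pins T2 at the bound and flags it", {
  mk_fit <- function(fat, te) {
    structure(list(areas = c(A = fat, B = 0, C = 0, D = 0, E = 0, F = 0,
                             water_narrow = fat, water_broad = 0), te = te),
              class = "peak_fit")
  }
  fits <- lapply(1:4, function(i) mk_fit(1 + 0.1 * i, c(12, 15, 20, 25)[i]))
  res <- t2_correct(fits)
  expect_equal(res$t2_fat, 1000)
  expect_match(res$flags[["fat"]], "bound")
})

test_that("PDFF edge cases follow the definition", {
  expect_equal(compute_pdff(0, 3), 0)
  expect_equal(compute_pdff(5, 0), 1)
  expect_equal(compute_pdff(2, 2), 0.5)
  expect_error(compute_pdff(0, 0), "undefined")
  expect_error(compute_pdff(-1, 1))
})

test_that("skipping T2 correction biases the single-TE fat fraction upward", {
  # water (T2 = 25 ms) decays faster than fat (80 ms): the apparent
  # signal fat fraction at any TE > 0 overshoots the proton-density value
  ss <- generate_spectrum(quick_spec(pdff_true = 0.32, snr = Inf,
                                     t2_fat = 80, t2_water = 25))
  fit_late <- fit_peaks(ss$spectra[[4]])
  sff <- sum(fit_late$areas[c("A", "B", "C", "D", "E", "F")]) /
    (sum(fit_late$areas[c("A", "B", "C", "D", "E", "F")]) +
       fit_late$areas[["water_narrow"]])
  expect_gt(sff, 0.32 + 0.03)
})
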