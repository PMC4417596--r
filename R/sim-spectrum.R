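## Forward model for multi-echo single-voxel marrow spectra.

#' Specification for a synthetic multi-echo spectrum set
#'
#' Parameters mirror a 3 T stimulated-echo acquisition with no water
#' suppression: four short echoes, 4096 complex points over a 5 kHz window.
#' The water signal is split into a narrow (long T2*) and a broad (short
#' T2*) component; the proton-density fat fraction (PDFF) ground truth is
#' defined against the narrow water component only.
#'
#' @param pdff_true generating fat fraction, in `[0, 1]`:
#'   fat / (fat + narrow water) at TE = 0.
#' @param te_list echo times in ms, strictly increasing, all > 0.
#' @param t2_fat,t2_water T2 relaxation times in ms (one value shared by all
#'   fat peaks, one shared by both water components).
#' @param linewidth_fat shared Gaussian FWHM of the fat peaks, Hz.
#' @param linewidth_water_narrow,linewidth_water_broad water FWHMs, Hz.
#' @param broad_water_fraction fraction of the total TE = 0 water area in
#'   the broad component, in `[0, 1)`.
#' @param snr amplitude signal-to-noise ratio: peak height of the main
#'   methylene (group B) resonance at the shortest TE divided by the noise
#'   standard deviation. `Inf` disables noise. When `pdff_true = 0` the
#'   narrow-water peak height is used as the reference instead.
#' @param field_strength Tesla.
#' @param n_points number of spectral points (>= 256).
#' @param bandwidth spectral width, Hz.
#' @param phase0 zero-order phase (radians) applied to the complex signal.
#' @param trig triglyceride proton model (see [triglyceride_protons()])
#'   fixing how fat area is distributed over the nine resonances.
#' @param seed integer seed making the noise realization reproducible.
#' @return object of class `spectrum_sim_spec`.
#' @export
spectrum_sim_spec <- function(pdff_true = 0.32,
                              te_list = c(12, 15, 20, 25),
                              t2_fat = 80,
                              t2_water = 25,
                              linewidth_fat = 25,
                              linewidth_water_narrow = 30,
                              linewidth_water_broad = 150,
                              broad_water_fraction = 0.25,
                              snr = Inf,
                              field_strength = 3,
                              n_points = 4096,
                              bandwidth = 5000,
                              phase0 = 0,
                              trig = triglyceride_protons(),
                              seed = 1L) {
  if (!is.numeric(pdff_true) || pdff_true < 0 || pdff_true > 1) {
    stop("pdff_true must lie in [0, 1]")
  }
  if (length(te_list) == 0 || any(te_list <= 0)) {
    stop("te_list must be nonempty with all echo times > 0")
  }
  if (any(diff(te_list) <= 0)) {
    stop("te_list must be strictly increasing (no duplicates)")
  }
  stopifnot(
    t2_fat > 0, t2_water > 0,
    linewidth_fat > 0, linewidth_water_narrow > 0, linewidth_water_broad > 0,
    broad_water_fraction >= 0, broad_water_fraction < 1,
    snr > 0, field_strength > 0, n_points >= 256, bandwidth > 0
  )
  structure(list(
    pdff_true = pdff_true, te_list = te_list,
    t2_fat = t2_fat, t2_water = t2_water,
    linewidth_fat = linewidth_fat,
    linewidth_water_narrow = linewidth_water_narrow,
    linewidth_water_broad = linewidth_water_broad,
    broad_water_fraction = broad_water_fraction,
    snr = snr, field_strength = field_strength,
    n_points = as.integer(n_points), bandwidth = bandwidth,
    phase0 = phase0, trig = trig, seed = as.integer(seed)
  ), class = "spectrum_sim_spec")
}

## TE = 0 areas (arbitrary units) implied by a generator spec.
## Total observable proton area (fat + all water) is fixed at 1000 so
## spectra from different specs live on a comparable scale.
spectrum_true_areas <- function(spec) {
  p <- spec$pdff_true
  bwf <- spec$broad_water_fraction
  ## pdff = fat / (fat + narrow water); narrow = (1 - bwf) * total water
  ## scale K solves fat + total water = 1000
  unit_water_total <- if (p >= 1) 0 else (1 - p) / (1 - bwf)
  k <- 1000 / (p + unit_water_total)
  fat_total <- k * p
  water_total <- k * unit_water_total
  water_narrow <- water_total * (1 - bwf)
  water_broad <- water_total * bwf
  per_peak_frac <- spec$trig$per_peak / sum(spec$trig$per_peak)
  group_tot <- vapply(split(per_peak_frac, FAT_PEAK_TABLE$group),
                      sum, numeric(1))
  list(
    fat_total = fat_total,
    fat_per_peak = fat_total * per_peak_frac,
    fat_per_group = fat_total * group_tot,
    water_narrow = water_narrow,
    water_broad = water_broad
  )
}

#' Generate a synthetic multi-echo spectrum set
#'
#' Produces one spectrum per echo time: nine Gaussian fat peaks (areas
#' allocated by the triglyceride proton model), plus narrow and broad water
#' peaks at 4.7 ppm. Areas decay as `exp(-TE / T2)` with the fat or water
#' T2; complex white Gaussian noise is added at the requested SNR. The
#' ground-truth record carries the TE = 0 group areas and the generating
#' PDFF, which equals `spec$pdff_true` by construction.
#'
#' @param spec a [spectrum_sim_spec()].
#' @return list of class `spectrum_set`: `spectra` (one `mrs_spectrum` per
#'   TE), `truth` (TE = 0 areas, PDFF, T2 values, constraint ratios),
#'   and `spec`.
#' @export
generate_spectrum <- function(spec) {
  stopifnot(inherits(spec, "spectrum_sim_spec"))
  areas0 <- spectrum_true_areas(spec)

  hz_step <- spec$bandwidth / spec$n_points
  ## spectral window centred mid-way through the 0-6 ppm region of interest
  centre_hz <- ppm_to_hz(3.0, spec$field_strength)
  hz_axis <- centre_hz + (seq_len(spec$n_points) - (spec$n_points + 1) / 2) * hz_step
  ppm_axis <- hz_axis / (spec$field_strength * GAMMA_1H_MHZ_PER_T)

  fat_hz <- ppm_to_hz(FAT_PEAK_TABLE$ppm, spec$field_strength)
  water_hz <- ppm_to_hz(WATER_PPM, spec$field_strength)

  ## noise reference: peak height of the largest methylene resonance (group
  ## B, 1.30 ppm) at the shortest TE; narrow water if there is no fat
  te_min <- min(spec$te_list)
  sigma_fat <- spec$linewidth_fat / (2 * sqrt(2 * log(2)))
  sigma_wn <- spec$linewidth_water_narrow / (2 * sqrt(2 * log(2)))
  ref_height <- if (spec$pdff_true > 0) {
    areas0$fat_per_peak[2] * exp(-te_min / spec$t2_fat) /
      (sigma_fat * sqrt(2 * pi))
  } else {
    areas0$water_narrow * exp(-te_min / spec$t2_water) /
      (sigma_wn * sqrt(2 * pi))
  }
  noise_sd <- if (is.finite(spec$snr)) ref_height / spec$snr else 0

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)

  spectra <- lapply(spec$te_list, function(te) {
    fat_areas <- areas0$fat_per_peak * exp(-te / spec$t2_fat)
    wn_area <- areas0$water_narrow * exp(-te / spec$t2_water)
    wb_area <- areas0$water_broad * exp(-te / spec$t2_water)
    profile <- rep(0, spec$n_points)
    for (i in seq_along(fat_hz)) {
      if (fat_areas[i] > 0) {
        profile <- profile +
          fat_areas[i] * gaussian_line(hz_axis, fat_hz[i], spec$linewidth_fat)
      }
    }
    if (wn_area > 0) {
      profile <- profile +
        wn_area * gaussian_line(hz_axis, water_hz, spec$linewidth_water_narrow)
    }
    if (wb_area > 0) {
      profile <- profile +
        wb_area * gaussian_line(hz_axis, water_hz, spec$linewidth_water_broad)
    }
    signal <- profile * exp(1i * spec$phase0)
    if (noise_sd > 0) {
      signal <- signal + complex(
        real = stats::rnorm(spec$n_points, 0, noise_sd),
        imaginary = stats::rnorm(spec$n_points, 0, noise_sd)
      )
    }
    mrs_spectrum(ppm_axis, signal, te = te,
                 field_strength = spec$field_strength,
                 bandwidth = spec$bandwidth)
  })

  denom <- areas0$fat_total + areas0$water_narrow
  truth <- list(
    pdff = if (denom > 0) areas0$fat_total / denom else NA_real_,
    fat_area_te0 = areas0$fat_total,
    fat_group_areas_te0 = areas0$fat_per_group,
    water_narrow_area_te0 = areas0$water_narrow,
    water_broad_area_te0 = areas0$water_broad,
    t2_fat = spec$t2_fat, t2_water = spec$t2_water,
    constraint_ratios = c(E = spec$trig$ratio_E, F = spec$trig$ratio_F),
    noise_sd = noise_sd
  )
  structure(list(spectra = spectra, truth = truth, spec = spec),
            class = "spectrum_set")
}

#' Construct a single-voxel spectrum object
#'
#' @param ppm monotonic chemical-shift axis (ppm, ascending here).
#' @param signal complex (or real) amplitudes, same length as `ppm`.
#' @param te echo time in ms (> 0).
#' @param field_strength Tesla.
#' @param bandwidth acquisition bandwidth, Hz.
#' @return object of class `mrs_spectrum`.
#' @export
mrs_spectrum <- function(ppm, signal, te, field_strength = 3,
                         bandwidth = NA_real_) {
  stopifnot(length(ppm) == length(signal), te > 0)
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) stop("ppm axis must be strictly monotonic")
  structure(list(ppm = ppm, signal = signal, te = te,
                 field_strength = field_strength, bandwidth = bandwidth),
            class = "mrs_spectrum")
}
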