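## Spectral model shared by the synthetic generator and the fitting routines:
## nine fat resonances grouped A-F plus two water components at 4.7 ppm.

#' Gyromagnetic ratio of the proton, MHz per Tesla
#' @keywords internal
GAMMA_1H_MHZ_PER_T <- 42.577

## Nominal chemical shifts (ppm) of the nine triglyceride resonances and
## their group labels. B, C and F are superpositions of two resonances each.
FAT_PEAK_TABLE <- data.frame(
  ppm   = c(0.90, 1.30, 1.59, 2.00, 2.25, 2.77, 4.20, 5.19, 5.31),
  group = c("A", "B", "B", "C", "C", "D", "E", "F", "F"),
  stringsAsFactors = FALSE
)

WATER_PPM <- 4.7

#' Proton counts of a triglyceride molecule per spectral group
#'
#' Allocates the proton signal of a triglyceride with mean fatty-acid chain
#' length `cl`, `ndb` double bonds and `nmidb` methylene-interrupted
#' (diallylic) double bonds per molecule to the nine marrow fat resonances,
#' then sums them into the six fitted groups (A: 0.90 ppm methyl;
#' B: 1.30 + 1.59 ppm methylene and beta-carboxyl; C: 2.00 + 2.25 ppm
#' allylic and alpha-carboxyl; D: 2.77 ppm diallylic; E: 4.20 ppm glycerol
#' CH2; F: 5.19 + 5.31 ppm glycerol CH and olefinic).
#'
#' The defaults describe a typical vertebral marrow triglyceride
#' (chain length 17.4, 2.8 double bonds, 0.7 methylene-interrupted).
#'
#' @param cl mean fatty-acid chain length (carbons).
#' @param ndb double bonds per triglyceride.
#' @param nmidb methylene-interrupted double bonds per triglyceride.
#' @return list with `per_peak` (9 proton counts, ordered as
#'   [FAT_PEAK_TABLE]), `per_group` (named A-F), and the constraint ratios
#'   `ratio_E` = E/(A+B) and `ratio_F` = F/(A+B).
#' @export
triglyceride_protons <- function(cl = 17.4, ndb = 2.8, nmidb = 0.7) {
  stopifnot(cl > 4, ndb >= 0, nmidb >= 0, nmidb <= ndb)
  per_peak <- c(
    9,                               # 0.90  -CH3
    6 * (cl - 4) - 8 * ndb + 2 * nmidb, # 1.30  -(CH2)n-
    6,                               # 1.59  -CO-CH2-CH2-
    4 * (ndb - nmidb),               # 2.00  -CH2-CH=CH-CH2-
    6,                               # 2.25  -CO-CH2-
    2 * nmidb,                       # 2.77  =CH-CH2-CH=
    4,                               # 4.20  glycerol CH2
    1,                               # 5.19  glycerol CH
    2 * ndb                          # 5.31  -CH=CH-
  )
  if (any(per_peak < 0)) {
    stop("triglyceride parameters give a negative proton count; ",
         "check cl/ndb/nmidb")
  }
  per_group <- vapply(split(per_peak, FAT_PEAK_TABLE$group), sum, numeric(1))
  ab <- per_group[["A"]] + per_group[["B"]]
  list(
    per_peak  = per_peak,
    per_group = per_group,
    ratio_E   = per_group[["E"]] / ab,
    ratio_F   = per_group[["F"]] / ab
  )
}

#' Constrained peak model for marrow spectra
#'
#' Describes the model fitted to each echo: nine Gaussian fat peaks with one
#' shared linewidth, two water peaks (narrow and broad) at 4.7 ppm with
#' independent linewidths, and the areas of groups E and F constrained to
#' fixed ratios of the area of A + B. Within-group area splits (for the
#' two-resonance groups B, C and F) are fixed at the triglyceride model's
#' proton proportions.
#'
#' @param constraint_ratios length-2 numeric, `c(E = ..., F = ...)`: area of
#'   group E (resp. F) as a multiple of area(A + B). Defaults come from
#'   [triglyceride_protons()].
#' @param trig triglyceride proton model used for within-group splits.
#' @param fat_location_bound ppm; fat peak centres may move at most this far.
#' @param water_location_bound ppm; water peak centres likewise.
#' @param linewidth_bounds Hz; lower/upper bounds for all fitted linewidths.
#' @param linewidth_init Hz; starting linewidths `c(fat, water_narrow,
#'   water_broad)`.
#' @return object of class `peak_model`.
#' @export
peak_model <- function(constraint_ratios = NULL,
                       trig = triglyceride_protons(),
                       fat_location_bound = 0.05,
                       water_location_bound = 0.50,
                       linewidth_bounds = c(1, 500),
                       linewidth_init = c(fat = 20, water_narrow = 20,
                                          water_broad = 100)) {
  if (is.null(constraint_ratios)) {
    constraint_ratios <- c(E = trig$ratio_E, F = trig$ratio_F)
  }
  stopifnot(all(constraint_ratios >= 0), length(constraint_ratios) == 2)
  ## within-group fractions of the two-resonance groups
  split_frac <- function(g) {
    p <- trig$per_peak[FAT_PEAK_TABLE$group == g]
    if (sum(p) == 0) rep(1 / length(p), length(p)) else p / sum(p)
  }
  structure(list(
    fat_ppm = FAT_PEAK_TABLE$ppm,
    fat_group = FAT_PEAK_TABLE$group,
    water_ppm = WATER_PPM,
    constraint_ratios = c(E = unname(constraint_ratios[1]),
                          F = unname(constraint_ratios[2])),
    group_split = list(A = 1, B = split_frac("B"), C = split_frac("C"),
                       D = 1, E = 1, F = split_frac("F")),
    fat_location_bound = fat_location_bound,
    water_location_bound = water_location_bound,
    linewidth_bounds = linewidth_bounds,
    linewidth_init = linewidth_init
  ), class = "peak_model")
}

#' Convert ppm to Hz at a given field strength
#' @param ppm chemical shift values.
#' @param field_strength Tesla.
#' @return frequencies in Hz.
#' @export
ppm_to_hz <- function(ppm, field_strength) {
  ppm * field_strength * GAMMA_1H_MHZ_PER_T
}

## Unit-area Gaussian on a Hz axis. fwhm in Hz; integral over Hz equals 1.
gaussian_line <- function(hz_axis, centre_hz, fwhm_hz) {
  sigma <- fwhm_hz / (2 * sqrt(2 * log(2)))
  exp(-((hz_axis - centre_hz)^2) / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
}
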