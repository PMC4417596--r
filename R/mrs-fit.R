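## Constrained Gaussian peak fitting of marrow spectra and T2-corrected
## proton-density fat fraction.
##
## The model at one echo is linear in the six free group areas
## (A, B, C, D, water_narrow, water_broad) once peak positions and the three
## linewidths are fixed: groups E and F enter as fixed multiples of
## area(A + B), so their lineshapes fold into the A and B basis columns.
## Fitting therefore uses variable projection: a bounded Levenberg-Marquardt
## search over the 14 nonlinear parameters (9 fat position offsets, 2 water
## position offsets, 3 linewidths), solving a non-negative least-squares
## problem for the areas at every step.

#' Zero-order phase correction of a complex spectrum
#'
#' Chooses the global phase that maximizes the integral of the real part
#' over the 0-6 ppm window (closed form: the argument of the complex
#' integral), and returns the spectrum with real-valued signal. Already
#' phased (real, net-positive) spectra are returned unchanged.
#'
#' @param spectrum an [mrs_spectrum()].
#' @return an `mrs_spectrum` with real `signal`; the applied phase is
#'   attached as attribute `phase_applied` (radians).
#' @export
phase_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "mrs_spectrum"))
  s <- spectrum$signal
  if (all(Mod(s) == 0)) stop("empty spectrum: signal is identically zero")
  win <- spectrum$ppm >= 0 & spectrum$ppm <= 6
  if (!any(win)) win <- rep(TRUE, length(s))
  z <- sum(s[win])
  phi <- Arg(z)
  out <- spectrum
  out$signal <- Re(s * exp(-1i * phi))
  attr(out, "phase_applied") <- phi
  out
}

## Build the six area-basis columns for given nonlinear parameters.
## theta: c(dfat[1:9], dwn, dwb, lw_fat, lw_wn, lw_wb); offsets in ppm,
## linewidths in Hz. Returns n_points x 6 matrix (A, B, C, D, wn, wb).
peak_basis <- function(theta, model, ppm, field_strength) {
  hz <- ppm * field_strength * GAMMA_1H_MHZ_PER_T
  dfat <- theta[1:9]; dwn <- theta[10]; dwb <- theta[11]
  lw_fat <- theta[12]; lw_wn <- theta[13]; lw_wb <- theta[14]
  fat_hz <- ppm_to_hz(model$fat_ppm + dfat, field_strength)

  peak_shapes <- matrix(0, length(ppm), 9)
  for (i in 1:9) peak_shapes[, i] <- gaussian_line(hz, fat_hz[i], lw_fat)

  group_col <- function(g) {
    idx <- which(model$fat_group == g)
    frac <- model$group_split[[g]]
    peak_shapes[, idx, drop = FALSE] %*% frac
  }
  col_a <- group_col("A"); col_b <- group_col("B")
  col_c <- group_col("C"); col_d <- group_col("D")
  col_e <- group_col("E"); col_f <- group_col("F")
  r_e <- model$constraint_ratios[["E"]]
  r_f <- model$constraint_ratios[["F"]]
  ## E and F areas are r_E, r_F times area(A+B): fold into the A, B columns
  basis <- cbind(
    as.numeric(col_a + r_e * col_e + r_f * col_f),
    as.numeric(col_b + r_e * col_e + r_f * col_f),
    as.numeric(col_c),
    as.numeric(col_d),
    gaussian_line(hz, ppm_to_hz(model$water_ppm + dwn, field_strength), lw_wn),
    gaussian_line(hz, ppm_to_hz(model$water_ppm + dwb, field_strength), lw_wb)
  )
  colnames(basis) <- c("A", "B", "C", "D", "wn", "wb")
  basis
}

## Non-negative least squares for the 6 area coefficients. Unconstrained
## QR is tried first; the active-set NNLS solver is only invoked when a
## coefficient comes out negative.
solve_areas <- function(basis, y) {
  areas <- .lm.fit(basis, y)$coefficients
  if (any(areas < 0)) areas <- pracma::lsqnonneg(basis, y)$x
  names(areas) <- colnames(basis)
  areas
}

#' Fit the constrained peak model to one spectrum
#'
#' Bounded nonlinear least squares of the nine-fat-peak, two-water model.
#' Fat peak positions may move by at most the model's fat location bound
#' (default 0.05 ppm), water positions by the water bound (default
#' 0.50 ppm); all fat peaks share one linewidth and each water component
#' has its own, so exactly three linewidths are free. The areas of groups
#' E and F are tied to area(A + B) by the model's constraint ratios, so the
#' returned `areas["E"]` and `areas["F"]` satisfy the constraints exactly
#' by construction. After fitting, the narrow/broad water labels are
#' assigned by linewidth (smaller fitted linewidth = narrow) so a label
#' swap during optimization cannot propagate.
#'
#' @param spectrum an [mrs_spectrum()] (complex input is phased first).
#' @param model a [peak_model()].
#' @param init optional named list overriding starting values:
#'   `linewidths` (Hz, length 3: fat, water narrow, water broad) and/or
#'   `offsets` (ppm, length 11: nine fat then two water). When `init` is
#'   supplied the linewidth-only pre-fit is skipped and the search starts
#'   from the given values.
#' @param fit_window ppm range actually fitted (the model peaks live in
#'   0-6 ppm; the default leaves margin for the broad water tails).
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @param ftol cost-reduction convergence tolerance.
#' @return object of class `peak_fit`: group areas (A-F, water_narrow,
#'   water_broad), fitted `linewidths` (Hz), fitted `locations` (ppm),
#'   `residual_norm`, `converged` flag, and the echo time `te`.
#' @details The search runs coarse-to-fine: the three linewidths are fitted
#'   first with all peak locations pinned at their nominal shifts, then all
#'   fourteen nonlinear parameters are released. Starting the location
#'   search from near-correct linewidths keeps the small constrained peaks
#'   (E, F) from driving their location offsets into the bounds.
#' @export
fit_peaks <- function(spectrum, model = peak_model(), init = NULL,
                      fit_window = c(-1, 7.5), max_iter = 2000,
                      ftol = 1e-10) {
  stopifnot(inherits(spectrum, "mrs_spectrum"), inherits(model, "peak_model"))
  if (is.complex(spectrum$signal)) spectrum <- phase_spectrum(spectrum)
  if (min(spectrum$ppm) > 0 || max(spectrum$ppm) < 6) {
    stop("spectrum must span the 0-6 ppm window covered by the peak model")
  }
  win <- spectrum$ppm >= fit_window[1] & spectrum$ppm <= fit_window[2]
  ppm <- spectrum$ppm[win]
  y <- as.numeric(spectrum$signal)[win]

  lw0 <- unname(unlist(model$linewidth_init))
  fb <- model$fat_location_bound; wbnd <- model$water_location_bound
  lower <- c(rep(-fb, 9), -wbnd, -wbnd, rep(model$linewidth_bounds[1], 3))
  upper <- c(rep(fb, 9), wbnd, wbnd, rep(model$linewidth_bounds[2], 3))

  resid_fun <- function(theta) {
    basis <- peak_basis(theta, model, ppm, spectrum$field_strength)
    areas <- solve_areas(basis, y)
    y - as.numeric(basis %*% areas)
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = min(max_iter, 1024),
                                     ftol = ftol, ptol = ftol)
  if (is.null(init)) {
    ## stage 1: linewidths only, locations nominal
    lw_fit <- minpack.lm::nls.lm(
      par = lw0, lower = rep(model$linewidth_bounds[1], 3),
      upper = rep(model$linewidth_bounds[2], 3),
      fn = function(lw) resid_fun(c(rep(0, 11), lw)), control = ctrl)
    theta0 <- c(rep(0, 11), lw_fit$par)
  } else {
    theta0 <- c(rep(0, 11), lw0)
    if (!is.null(init$offsets)) theta0[1:11] <- init$offsets
    if (!is.null(init$linewidths)) theta0[12:14] <- init$linewidths
    theta0 <- pmin(pmax(theta0, lower), upper)
  }
  ## stage 2: all nonlinear parameters free
  lm_fit <- minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                               fn = resid_fun, control = ctrl)
  theta <- lm_fit$par
  basis <- peak_basis(theta, model, ppm, spectrum$field_strength)
  coefs <- solve_areas(basis, y)
  resid <- y - as.numeric(basis %*% coefs)

  r_e <- model$constraint_ratios[["E"]]
  r_f <- model$constraint_ratios[["F"]]
  ab <- coefs[["A"]] + coefs[["B"]]
  areas <- c(A = coefs[["A"]], B = coefs[["B"]], C = coefs[["C"]],
             D = coefs[["D"]], E = r_e * ab, F = r_f * ab,
             water_narrow = NA_real_, water_broad = NA_real_)
  ## narrow/broad identity by fitted linewidth, not by parameter slot
  if (theta[13] <= theta[14]) {
    areas["water_narrow"] <- coefs[["wn"]]; areas["water_broad"] <- coefs[["wb"]]
    lw_wn <- theta[13]; lw_wb <- theta[14]
    loc_wn <- model$water_ppm + theta[10]; loc_wb <- model$water_ppm + theta[11]
  } else {
    areas["water_narrow"] <- coefs[["wb"]]; areas["water_broad"] <- coefs[["wn"]]
    lw_wn <- theta[14]; lw_wb <- theta[13]
    loc_wn <- model$water_ppm + theta[11]; loc_wb <- model$water_ppm + theta[10]
  }
  converged <- lm_fit$info %in% 1:4
  structure(list(
    areas = areas,
    linewidths = c(fat = theta[12], water_narrow = lw_wn, water_broad = lw_wb),
    locations = c(stats::setNames(model$fat_ppm + theta[1:9],
                                  paste0("fat_", model$fat_ppm)),
                  water_narrow = loc_wn, water_broad = loc_wb),
    residual_norm = sqrt(sum(resid^2)),
    converged = converged,
    lm_info = lm_fit$info,
    te = spectrum$te
  ), class = "peak_fit")
}

## Mono-exponential area decay fit: area(te) = a0 * exp(-te / t2).
## Returns list(a0, t2, flag). Bounds t2 in [1, 1000] ms.
fit_exp_decay <- function(areas, te_list, t2_bounds = c(1, 1000)) {
  stopifnot(length(areas) == length(te_list))
  if (any(areas < 0)) stop("negative areas passed to T2 fitting")
  flag <- "ok"
  if (all(areas <= .Machine$double.eps * 100)) {
    return(list(a0 = 0, t2 = NA_real_, flag = "zero_area"))
  }
  if (length(te_list) == 2) {
    ## exactly determined two-point closed form
    if (areas[2] >= areas[1]) {
      t2 <- t2_bounds[2]; flag <- "non_decaying_two_point"
    } else {
      t2 <- (te_list[2] - te_list[1]) / log(areas[1] / areas[2])
      t2 <- min(max(t2, t2_bounds[1]), t2_bounds[2])
      flag <- "two_point"
    }
    return(list(a0 = areas[1] * exp(te_list[1] / t2), t2 = t2, flag = flag))
  }
  ## log-linear start (positive areas only)
  pos <- areas > 0
  if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(areas[pos]) ~ te_list[pos]))
    t2_start <- if (sl[2] < 0) min(max(-1 / sl[2], t2_bounds[1]), t2_bounds[2])
                else t2_bounds[2]
    a0_start <- exp(sl[1])
  } else {
    t2_start <- 50; a0_start <- max(areas)
  }
  fit <- minpack.lm::nls.lm(
    par = c(a0 = a0_start, t2 = t2_start),
    lower = c(0, t2_bounds[1]), upper = c(Inf, t2_bounds[2]),
    fn = function(p) areas - p[1] * exp(-te_list / p[2]),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12)
  )
  a0 <- fit$par[[1]]; t2 <- fit$par[[2]]
  if (t2 >= t2_bounds[2] - 1e-9) flag <- "t2_at_upper_bound"
  list(a0 = a0, t2 = t2, flag = flag)
}

#' T2 correction of per-echo peak areas
#'
#' Fits mono-exponential decays `area(TE) = area0 * exp(-TE / T2)` by
#' nonlinear least squares, separately for the total fat area (sum of
#' groups A-F, one shared fat T2) and for the narrow water area, then
#' computes the proton-density fat fraction from the TE-extrapolated areas
#' via [compute_pdff()]. With exactly two echoes the closed-form two-point
#' solution is used and flagged; a non-decaying area sequence pins T2 at
#' the upper bound (1000 ms) and is flagged, never silently accepted.
#'
#' @param fits list of [fit_peaks()] results, one per echo.
#' @param te_list echo times in ms matching `fits` (default: taken from the
#'   fits themselves).
#' @return object of class `t2_corrected`: `t2_fat`, `t2_water` (ms),
#'   `area_fat_te0`, `area_water_narrow_te0`, `pdff`, per-echo observed and
#'   fitted areas, and decay-fit flags.
#' @export
t2_correct <- function(fits, te_list = vapply(fits, `[[`, numeric(1), "te")) {
  stopifnot(length(fits) >= 2, length(te_list) == length(fits))
  if (length(fits) < 3) {
    warning("only two echo times: T2 from the two-point closed form")
  }
  fat_areas <- vapply(fits, function(f)
    sum(f$areas[c("A", "B", "C", "D", "E", "F")]), numeric(1))
  wn_areas <- vapply(fits, function(f) f$areas[["water_narrow"]], numeric(1))

  fat_fit <- fit_exp_decay(fat_areas, te_list)
  wn_fit <- fit_exp_decay(wn_areas, te_list)

  pdff <- compute_pdff(fat_fit$a0, wn_fit$a0)
  structure(list(
    t2_fat = fat_fit$t2, t2_water = wn_fit$t2,
    area_fat_te0 = fat_fit$a0, area_water_narrow_te0 = wn_fit$a0,
    pdff = pdff,
    te = te_list,
    observed = list(fat = fat_areas, water_narrow = wn_areas),
    fitted = list(
      fat = fat_fit$a0 * exp(-te_list / ifelse(is.na(fat_fit$t2), Inf, fat_fit$t2)),
      water_narrow = wn_fit$a0 * exp(-te_list / ifelse(is.na(wn_fit$t2), Inf, wn_fit$t2))
    ),
    flags = c(fat = fat_fit$flag, water = wn_fit$flag)
  ), class = "t2_corrected")
}

#' Proton-density fat fraction
#'
#' PDFF = fat / (fat + narrow water), both areas extrapolated to TE = 0.
#' The broad (short T2*) water component is excluded by definition.
#'
#' @param area_fat_te0 total fat area at TE = 0 (groups A-F).
#' @param area_water_narrow_te0 narrow-water area at TE = 0.
#' @return fat fraction in `[0, 1]`.
#' @export
compute_pdff <- function(area_fat_te0, area_water_narrow_te0) {
  stopifnot(area_fat_te0 >= 0, area_water_narrow_te0 >= 0)
  total <- area_fat_te0 + area_water_narrow_te0
  if (total == 0) stop("PDFF undefined: fat and narrow water areas both zero")
  area_fat_te0 / total
}

#' Full spectroscopy pipeline: phase, fit each echo, T2-correct
#'
#' @param spectra list of [mrs_spectrum()] objects at distinct echo times
#'   (or a `spectrum_set` from [generate_spectrum()]).
#' @param model a [peak_model()].
#' @param ... passed to [fit_peaks()].
#' @return a `t2_corrected` result with the per-echo `peak_fit`s attached
#'   as `$peak_fits`.
#' @export
fit_pdff <- function(spectra, model = peak_model(), ...) {
  if (inherits(spectra, "spectrum_set")) spectra <- spectra$spectra
  fits <- lapply(spectra, fit_peaks, model = model, ...)
  out <- t2_correct(fits)
  out$peak_fits <- fits
  out
}
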