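## QCT calibration and trabecular morphometry: BMD, BV/TV, trabecular
## number via the mean intercept length method, box-counting fractal
## dimension, and cross-sectional areas.

#' Phantom-based HU-to-density calibration
#'
#' Ordinary least squares of nominal phantom density on measured mean HU.
#'
#' @param phantom_pairs data.frame (or 2-column matrix) with columns
#'   `hu` (measured mean attenuation, HU) and `density` (nominal rod
#'   density, mg/cm^3); at least two rods with distinct HU.
#' @return object of class `qct_calibration`: `slope` ((mg/cm^3)/HU),
#'   `intercept` (mg/cm^3), `r_squared`, and the input pairs.
#' @export
calibrate <- function(phantom_pairs) {
  pp <- as.data.frame(phantom_pairs)
  if (!all(c("hu", "density") %in% names(pp))) {
    names(pp)[1:2] <- c("hu", "density")
  }
  if (nrow(pp) < 2) stop("need at least two phantom rods")
  if (length(unique(pp$hu)) < 2) {
    stop("identical HU values across phantom rods: calibration is singular")
  }
  fit <- stats::lm(density ~ hu, data = pp)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    pairs = pp
  ), class = "qct_calibration")
}

#' Apply a calibration model to an HU volume
#'
#' @param hu 3D array of attenuations (HU).
#' @param model a `qct_calibration`.
#' @return 3D array of densities, mg/cm^3, same shape.
#' @export
apply_calibration <- function(hu, model) {
  stopifnot(inherits(model, "qct_calibration"))
  model$slope * hu + model$intercept
}

#' Place a centred rectangular ROI over the most central slices
#'
#' The in-plane window spans `extent_mm` per axis, converted to voxels by
#' nearest-integer rounding with ties toward the larger window, centred on
#' the specimen (mask centroid if a mask is given, volume centre
#' otherwise). The `n_slices` most central z-slices are selected.
#'
#' @param dim_vol integer volume dimensions `c(nx, ny, nz)`.
#' @param voxel_size mm per axis.
#' @param extent_mm in-plane ROI edge length, mm (default 12 x 12 mm^2).
#' @param n_slices number of central slices (default 20).
#' @param mask optional logical array (same shape) whose centroid centres
#'   the ROI; `center` overrides.
#' @param center optional explicit in-plane centre (voxel coordinates).
#' @return list of class `roi`: integer index vectors `x`, `y`, `z`.
#' @export
place_roi <- function(dim_vol, voxel_size, extent_mm = 12, n_slices = 20,
                      mask = NULL, center = NULL) {
  stopifnot(length(dim_vol) == 3, all(voxel_size > 0), n_slices >= 1)
  ## nearest integer, ties toward the larger window (floor(x + .5) rounds
  ## halves up, unlike round()'s round-half-even)
  n_vox <- pmax(1L, as.integer(floor(extent_mm / voxel_size[1:2] + 0.5)))
  if (is.null(center)) {
    center <- if (!is.null(mask)) {
      idx <- which(mask, arr.ind = TRUE)
      if (nrow(idx) == 0) stop("specimen mask is empty")
      c(mean(idx[, 1]), mean(idx[, 2]))
    } else {
      (dim_vol[1:2] + 1) / 2
    }
  }
  start <- as.integer(round(center - (n_vox - 1) / 2))
  for (a in 1:2) {
    rng <- start[a]:(start[a] + n_vox[a] - 1L)
    if (rng[1] < 1 || rng[length(rng)] > dim_vol[a]) {
      stop("ROI exceeds volume bounds on axis ", c("x", "y")[a])
    }
  }
  nz <- dim_vol[3]
  if (n_slices > nz) stop("ROI exceeds volume bounds on axis z: ",
                          n_slices, " slices requested, ", nz, " available")
  z_start <- (nz - n_slices) %/% 2L + 1L
  structure(list(
    x = start[1]:(start[1] + n_vox[1] - 1L),
    y = start[2]:(start[2] + n_vox[2] - 1L),
    z = z_start:(z_start + n_slices - 1L)
  ), class = "roi")
}

roi_values <- function(volume, roi) volume[roi$x, roi$y, roi$z, drop = FALSE]

#' Mean bone mineral density in an ROI
#'
#' @param density_volume 3D density array, mg/cm^3.
#' @param roi an `roi` from [place_roi()] (or `NULL` for the full volume).
#' @return mean density, mg/cm^3.
#' @export
mean_bmd <- function(density_volume, roi = NULL) {
  vals <- if (is.null(roi)) density_volume else roi_values(density_volume, roi)
  if (length(vals) == 0) stop("empty ROI")
  mean(vals)
}

#' Binarize a density volume at a global threshold
#'
#' Bone is `density >= threshold` — the boundary value itself counts as
#' bone (inclusive rule).
#'
#' @param density_volume 3D density array, mg/cm^3.
#' @param threshold mg/cm^3; default 200 (calcium hydroxyapatite).
#' @return logical array, `TRUE` = bone.
#' @export
binarize <- function(density_volume, threshold = 200) {
  stopifnot(is.finite(threshold))
  density_volume >= threshold
}

#' Bone volume fraction
#'
#' @param binary_roi logical array, `TRUE` = bone.
#' @return BV/TV in percent.
#' @export
bv_tv <- function(binary_roi) {
  if (length(binary_roi) == 0) stop("empty ROI")
  100 * sum(binary_roi) / length(binary_roi)
}

## Direction-wise line statistics: total bone length, strict wrap-free
## marrow-to-bone transition count, and the number of lines containing bone.
mil_direction <- function(mask, voxel_size, axis) {
  d <- dim(mask)
  n <- d[axis]
  step <- voxel_size[axis]
  bone_len <- sum(mask) * step
  ## shift mask one voxel along `axis`
  shifted <- switch(axis,
    mask[c(NA, seq_len(n - 1)), , , drop = FALSE],
    mask[, c(NA, seq_len(n - 1)), , drop = FALSE],
    mask[, , c(NA, seq_len(n - 1)), drop = FALSE])
  trans <- sum(mask & !shifted, na.rm = TRUE)
  lines_with_bone <- switch(axis,
    sum(apply(mask, c(2, 3), any)),
    sum(apply(mask, c(1, 3), any)),
    sum(apply(mask, c(1, 2), any)))
  list(bone_length = bone_len, transitions = trans,
       lines_with_bone = lines_with_bone,
       mil = if (trans > 0) bone_len / trans
             else if (lines_with_bone > 0) bone_len / lines_with_bone
             else NA_real_)
}

#' Mean intercept length and trabecular number
#'
#' Casts one test line per voxel row along each requested axis, using
#' physical (anisotropy-aware) lengths. Per direction,
#' `MIL = total bone length / number of marrow-to-bone transitions`,
#' transitions counted strictly and wrap-free (a bone run starting a line
#' is not an entry). Along a direction with no transitions at all (lines
#' parallel to plates), MIL degrades to the mean bone length of the lines
#' that contain bone, i.e. the full line length for solid bone rows.
#'
#' Mean trabecular plate thickness is the direction-averaged MIL and the
#' trabecular number follows the plate-model closure
#' `TbN = (BV/TV) / Tb.Th*`.
#'
#' @param binary_roi logical 3D array, `TRUE` = bone; must contain both
#'   phases.
#' @param voxel_size mm per axis.
#' @param directions subset of `c("x", "y", "z")`.
#' @return list of class `mil_result`: per-direction `mil` (mm),
#'   `tb_th` (direction-averaged MIL, mm), `tbn` (mm^-1), `bv_tv` (%), and
#'   the per-direction `bone_length` / `transitions` /
#'   `lines_with_bone` counts for audit.
#' @export
mil_tbn <- function(binary_roi, voxel_size, directions = c("x", "y", "z")) {
  stopifnot(length(dim(binary_roi)) == 3, all(voxel_size > 0))
  directions <- match.arg(directions, c("x", "y", "z"), several.ok = TRUE)
  nb <- sum(binary_roi)
  if (nb == 0 || nb == length(binary_roi)) {
    stop("MIL undefined: ROI is entirely ", if (nb == 0) "marrow" else "bone")
  }
  per_dir <- lapply(match(directions, c("x", "y", "z")),
                    function(a) mil_direction(binary_roi, voxel_size, a))
  names(per_dir) <- directions
  mils <- vapply(per_dir, `[[`, numeric(1), "mil")
  tb_th <- mean(mils)
  bvtv <- bv_tv(binary_roi)
  structure(list(
    mil = mils,
    tb_th = tb_th,
    tbn = (bvtv / 100) / tb_th,
    bv_tv = bvtv,
    counts = lapply(per_dir, function(p)
      p[c("bone_length", "transitions", "lines_with_bone")])
  ), class = "mil_result")
}

## Box count of one binary slice at one box size: number of s x s grid
## cells (anchored at (1,1); partial cells at the far edges count too)
## containing at least one TRUE pixel.
count_boxes <- function(slice, s) {
  idx <- which(slice, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0L)
  nrow(unique.matrix(cbind((idx[, 1] - 1L) %/% s, (idx[, 2] - 1L) %/% s)))
}

#' Box-counting fractal dimension of binary slices
#'
#' For each transverse slice, counts occupied boxes `N(s)` over the box
#' sizes and fits the least-squares slope of `log N(s)` against
#' `log(1 / s)`; the result is the mean slope over slices. Slices with no
#' bone pixels are excluded with a warning. Counting uses the bone mask
#' itself (not its boundary); boxes clipped by the slice border still
#' count when they contain bone.
#'
#' @param slices logical 3D array (slices along the third axis) or a list
#'   of logical matrices.
#' @param box_sizes box edge lengths in pixels, >= 3 sizes (default powers
#'   of two, 2 to 64).
#' @return list of class `fd_result`: `fd` (mean over slices), `per_slice`
#'   (per-slice FD), and `counts` (per-slice `N(s)` matrix).
#' @export
fractal_dimension <- function(slices, box_sizes = 2^(1:6)) {
  if (length(box_sizes) < 3) stop("need at least three box sizes")
  if (is.array(slices) && length(dim(slices)) == 3) {
    slices <- lapply(seq_len(dim(slices)[3]), function(k) slices[, , k])
  }
  if (is.matrix(slices)) slices <- list(slices)
  keep <- vapply(slices, function(m) sum(m) > 0, logical(1))
  if (!any(keep)) stop("all slices contain zero bone pixels")
  if (!all(keep)) {
    warning(sum(!keep), " slice(s) with zero bone pixels excluded from FD")
  }
  slices <- slices[keep]
  counts <- t(vapply(slices, function(m)
    vapply(box_sizes, function(s) as.numeric(count_boxes(m, s)), numeric(1)),
    numeric(length(box_sizes))))
  log_inv_s <- log(1 / box_sizes)
  per_slice <- apply(counts, 1, function(n) {
    unname(stats::coef(stats::lm(log(n) ~ log_inv_s))[2])
  })
  structure(list(fd = mean(per_slice), per_slice = per_slice,
                 counts = counts, box_sizes = box_sizes),
            class = "fd_result")
}

#' Mean and minimum transverse cross-sectional area
#'
#' Per-slice area is the pixel count times the in-plane voxel area; the
#' mean and minimum are taken over nonempty slices.
#'
#' @param specimen_mask logical 3D array (slices along the third axis).
#' @param voxel_size mm per axis.
#' @return list: `mean_area` and `min_area` in cm^2, and `per_slice`
#'   (cm^2, `NA` for empty slices).
#' @export
cross_sectional_areas <- function(specimen_mask, voxel_size) {
  stopifnot(length(dim(specimen_mask)) == 3, all(voxel_size > 0))
  px_area_cm2 <- voxel_size[1] * voxel_size[2] / 100  # mm^2 -> cm^2
  counts <- apply(specimen_mask, 3, sum)
  if (all(counts == 0)) stop("specimen mask is empty")
  areas <- ifelse(counts > 0, counts * px_area_cm2, NA_real_)
  list(mean_area = mean(areas, na.rm = TRUE),
       min_area = min(areas, na.rm = TRUE),
       per_slice = areas)
}

#' Full morphometry of a calibrated synthetic or measured volume
#'
#' Convenience composition: calibrate from phantom ROIs, convert to
#' density, place the central ROI, and compute BMD, BV/TV, TbN and FD.
#'
#' @param hu 3D HU array.
#' @param voxel_size mm per axis.
#' @param phantom_pairs data.frame with `hu` and `density` columns.
#' @param threshold binarization threshold, mg/cm^3.
#' @param roi an `roi`; default: 12 mm window over the 20 most central
#'   slices of the full volume.
#' @param directions MIL directions.
#' @param box_sizes FD box sizes.
#' @return list of class `morphometry_result` with `bmd`, `bv_tv`, `tbn`,
#'   `fd` plus the intermediate `calibration` and `roi`.
#' @export
morphometry <- function(hu, voxel_size, phantom_pairs, threshold = 200,
                        roi = NULL, directions = c("x", "y", "z"),
                        box_sizes = 2^(1:6)) {
  cal <- calibrate(phantom_pairs)
  density <- apply_calibration(hu, cal)
  if (is.null(roi)) {
    roi <- place_roi(dim(hu), voxel_size,
                     n_slices = min(20L, dim(hu)[3]))
  }
  dens_roi <- roi_values(density, roi)
  mask_roi <- binarize(dens_roi, threshold)
  mil <- mil_tbn(mask_roi, voxel_size, directions)
  fd <- fractal_dimension(mask_roi, box_sizes)
  structure(list(
    bmd = mean(dens_roi),
    bv_tv = bv_tv(mask_roi),
    tbn = mil$tbn,
    fd = fd$fd,
    mil = mil,
    calibration = cal,
    roi = roi,
    threshold = threshold
  ), class = "morphometry_result")
}
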