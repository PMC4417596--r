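## Synthetic HU-encoded CT volumes: an axis-aligned trabecular lattice with
## analytically known morphometry, plus an embedded calibration phantom.

#' Specification for a synthetic trabecular CT volume
#'
#' The volume holds a plate or rod lattice (bone at `bone_density`, marrow
#' elsewhere) in its upper y-rows and a calibration phantom — blocks of
#' known density spanning all slices — in its bottom y-rows, mimicking a
#' phantom lying in the scanner mat beneath the specimen. Densities are
#' encoded to HU with the given affine map (`hu = (density - intercept) /
#' slope`, the inverse of the calibration `density = slope * hu +
#' intercept`) and optional white HU noise.
#'
#' @param shape integer voxel counts `c(nx, ny, nz)`.
#' @param voxel_size mm per axis; default the scanner's effective
#'   resolution 0.23 x 0.23 x 0.6 mm.
#' @param lattice list: `type` ("plate" or "rod"), `thickness` and
#'   `spacing` in mm (marrow gap between structures), `orientation`
#'   ("x", "y" or "z", the normal of the plates / the two axes a rod grid
#'   spans).
#' @param bone_density,marrow_density mg/cm^3 calcium hydroxyapatite.
#' @param phantom_densities strictly increasing rod densities, mg/cm^3,
#'   length >= 2.
#' @param calibration_slope,calibration_intercept the density-per-HU map
#'   the volume is encoded with ((mg/cm^3)/HU and mg/cm^3).
#' @param noise_sd_hu white Gaussian noise on the HU volume.
#' @param allow_subvoxel generate even when thickness or spacing round to
#'   less than one voxel (ground truth then undefined; off by default).
#' @param seed integer noise seed.
#' @return object of class `volume_sim_spec`.
#' @export
volume_sim_spec <- function(shape = c(64, 64, 32),
                            voxel_size = c(0.23, 0.23, 0.6),
                            lattice = list(type = "plate", thickness = 0.23,
                                           spacing = 0.69, orientation = "x"),
                            bone_density = 300,
                            marrow_density = 50,
                            phantom_densities = c(0, 100, 200, 400),
                            calibration_slope = 1.2,
                            calibration_intercept = -10,
                            noise_sd_hu = 0,
                            allow_subvoxel = FALSE,
                            seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 8),
            length(voxel_size) == 3, all(voxel_size > 0),
            length(phantom_densities) >= 2,
            all(diff(phantom_densities) > 0),
            is.finite(calibration_slope), calibration_slope != 0,
            noise_sd_hu >= 0)
  lattice$type <- match.arg(lattice$type, c("plate", "rod"))
  lattice$orientation <- match.arg(lattice$orientation, c("x", "y", "z"))
  axis_vox <- voxel_size[match(lattice$orientation, c("x", "y", "z"))]
  th_vox <- round(lattice$thickness / axis_vox)
  sp_vox <- round(lattice$spacing / axis_vox)
  if ((th_vox < 1 || sp_vox < 1) && !allow_subvoxel) {
    stop("lattice thickness and spacing must each cover at least one voxel; ",
         "set allow_subvoxel = TRUE to override")
  }
  structure(list(
    shape = as.integer(shape), voxel_size = voxel_size, lattice = lattice,
    bone_density = bone_density, marrow_density = marrow_density,
    phantom_densities = phantom_densities,
    calibration_slope = calibration_slope,
    calibration_intercept = calibration_intercept,
    noise_sd_hu = noise_sd_hu, allow_subvoxel = allow_subvoxel,
    seed = as.integer(seed)
  ), class = "volume_sim_spec")
}

## 1D on/off lattice pattern of length n: marrow-led period of
## (thickness, spacing) voxels, first structure starting at index 2 so test
## lines enter through marrow.
lattice_pattern <- function(n, th_vox, sp_vox) {
  period <- th_vox + sp_vox
  idx <- (seq_len(n) - 2L) %% period
  idx < th_vox & seq_len(n) >= 2L
}

## Analytic MIL of a 1D pattern along its own axis, plus transition count.
## Strict wrap-free marrow-to-bone counting, same convention as mil_tbn();
## generated patterns always start with marrow so no run is left uncounted.
pattern_mil <- function(pattern, step_mm) {
  bone <- sum(pattern)
  trans <- sum(pattern[-1] & !pattern[-length(pattern)])
  if (trans == 0) return(list(mil = NA_real_, transitions = 0L))
  list(mil = bone * step_mm / trans, transitions = as.integer(trans))
}

#' Generate a synthetic HU volume with known morphometry ground truth
#'
#' @param spec a [volume_sim_spec()].
#' @return list of class `volume_sim`: `hu` (3D array), `voxel_size`, and
#'   `truth` carrying the exact bone mask of the lattice region, its BV/TV
#'   (%), per-axis expected MIL (mm, `NA` where no transitions occur along
#'   the axis, i.e. lines parallel to the plates), the phantom block index
#'   ranges with their densities, the lattice-region index ranges, and the
#'   encoding slope/intercept.
#' @export
generate_volume <- function(spec) {
  stopifnot(inherits(spec, "volume_sim_spec"))
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  vx <- spec$voxel_size
  lat <- spec$lattice
  ax_i <- match(lat$orientation, c("x", "y", "z"))
  th_vox <- max(1L, round(lat$thickness / vx[ax_i]))
  sp_vox <- max(1L, round(lat$spacing / vx[ax_i]))

  ## bottom y-rows: phantom; a marrow gap; the rest is the lattice region
  n_phantom_rows <- max(4L, ceiling(2 / vx[2]))  # ~2 mm of phantom
  gap_rows <- 2L
  lattice_y <- seq_len(ny - n_phantom_rows - gap_rows)
  phantom_y <- seq(ny - n_phantom_rows + 1L, ny)
  if (length(lattice_y) < 8) stop("volume too small to hold lattice and phantom")

  lat_dim <- c(nx, length(lattice_y), nz)
  pat <- lattice_pattern(lat_dim[ax_i], th_vox, sp_vox)
  mask <- array(FALSE, lat_dim)
  if (lat$type == "plate") {
    if (ax_i == 1) mask[pat, , ] <- TRUE
    if (ax_i == 2) mask[, pat, ] <- TRUE
    if (ax_i == 3) mask[, , pat] <- TRUE
  } else {
    ## rods run along `orientation`; the two perpendicular axes carry the
    ## on/off pattern, bone where both are "on"
    perp <- setdiff(1:3, ax_i)
    pat1 <- lattice_pattern(lat_dim[perp[1]], th_vox, sp_vox)
    pat2 <- lattice_pattern(lat_dim[perp[2]], th_vox, sp_vox)
    on <- list(NULL, NULL, NULL)
    on[[ax_i]] <- rep(TRUE, lat_dim[ax_i])
    on[[perp[1]]] <- pat1; on[[perp[2]]] <- pat2
    mask <- array(outer(outer(on[[1]], on[[2]]), on[[3]]), lat_dim)
  }

  density <- array(spec$marrow_density, c(nx, ny, nz))
  density[, lattice_y, ][mask] <- spec$bone_density

  ## phantom: contiguous x-blocks, one per density, spanning all slices
  nd <- length(spec$phantom_densities)
  edges <- floor(seq(0, nx, length.out = nd + 1))
  phantom_blocks <- lapply(seq_len(nd), function(k) {
    xr <- (edges[k] + 1L):edges[k + 1L]
    density[xr, phantom_y, ] <<- spec$phantom_densities[k]
    list(x = range(xr), y = range(phantom_y), z = c(1L, nz),
         density = spec$phantom_densities[k])
  })

  hu <- (density - spec$calibration_intercept) / spec$calibration_slope
  if (spec$noise_sd_hu > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(spec$seed)
    hu <- hu + array(stats::rnorm(length(hu), 0, spec$noise_sd_hu), dim(hu))
  }

  ## analytic per-axis MIL of the lattice region
  mil <- c(x = NA_real_, y = NA_real_, z = NA_real_)
  if (lat$type == "plate") {
    mil[ax_i] <- pattern_mil(pat, vx[ax_i])$mil
  } else {
    perp <- setdiff(1:3, ax_i)
    mil[perp[1]] <- pattern_mil(lattice_pattern(lat_dim[perp[1]], th_vox, sp_vox),
                                vx[perp[1]])$mil
    mil[perp[2]] <- pattern_mil(lattice_pattern(lat_dim[perp[2]], th_vox, sp_vox),
                                vx[perp[2]])$mil
  }

  truth <- list(
    mask = mask,
    lattice_region = list(x = c(1L, nx), y = range(lattice_y), z = c(1L, nz)),
    bv_tv = 100 * sum(mask) / length(mask),
    mil = mil,
    phantom = phantom_blocks,
    slope = spec$calibration_slope,
    intercept = spec$calibration_intercept
  )
  structure(list(hu = hu, voxel_size = vx, truth = truth, spec = spec),
            class = "volume_sim")
}
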