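## Plain-text interchange: spectra as CSV + JSON sidecar, volumes as
## NIfTI, curves and cohort tables as CSV.

#' Write a spectrum set to CSV files with JSON sidecars
#'
#' One `spectrum_te<TE>.csv` (columns `ppm`, `real`, `imag`) and one
#' matching `.json` sidecar (TE ms, field T, bandwidth Hz, n points) per
#' echo.
#'
#' @param spectra list of `mrs_spectrum` objects (or a `spectrum_set`).
#' @param dir output directory, created if needed.
#' @return invisibly, the CSV paths written.
#' @export
write_spectra <- function(spectra, dir) {
  if (inherits(spectra, "spectrum_set")) spectra <- spectra$spectra
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(spectra, function(sp) {
    stem <- file.path(dir, sprintf("spectrum_te%g", sp$te))
    utils::write.csv(data.frame(ppm = sp$ppm, real = Re(sp$signal),
                                imag = Im(sp$signal)),
                     paste0(stem, ".csv"), row.names = FALSE)
    jsonlite::write_json(
      list(te_ms = sp$te, field_strength_t = sp$field_strength,
           bandwidth_hz = sp$bandwidth, n_points = length(sp$ppm)),
      paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
    paste0(stem, ".csv")
  }, character(1))
  invisible(paths)
}

#' Read a spectrum set written by [write_spectra()]
#'
#' @param dir directory holding `spectrum_te*.csv` and sidecars.
#' @return list of `mrs_spectrum` objects ordered by echo time.
#' @export
read_spectra <- function(dir) {
  csvs <- list.files(dir, pattern = "^spectrum_te.*\\.csv$",
                     full.names = TRUE)
  if (length(csvs) == 0) stop("no spectrum CSV files found in ", dir)
  spectra <- lapply(csvs, function(path) {
    tab <- utils::read.csv(path)
    meta <- jsonlite::read_json(sub("\\.csv$", ".json", path))
    mrs_spectrum(tab$ppm, complex(real = tab$real, imaginary = tab$imag),
                 te = meta$te_ms, field_strength = meta$field_strength_t,
                 bandwidth = meta$bandwidth_hz)
  })
  spectra[order(vapply(spectra, `[[`, numeric(1), "te"))]
}

#' Write a volume as NIfTI with voxel size in the header
#'
#' @param volume 3D numeric array (HU or density).
#' @param voxel_size mm per axis.
#' @param path output `.nii` / `.nii.gz` path.
#' @return invisibly, `path`.
#' @export
write_volume_nifti <- function(volume, voxel_size, path) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume and its voxel size
#'
#' @param path `.nii` / `.nii.gz` file.
#' @return list: `values` (3D array), `voxel_size` (mm per axis).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = unclass(img)[, , , drop = FALSE],
       voxel_size = RNifti::pixdim(img)[1:3])
}

#' Write / read a load-displacement curve as CSV
#'
#' Columns `displacement_mm`, `load_n`.
#' @param curve a `load_curve`.
#' @param path CSV path.
#' @return invisibly `path` (write); a `load_curve` (read).
#' @export
write_load_curve <- function(curve, path) {
  utils::write.csv(data.frame(displacement_mm = curve$displacement,
                              load_n = curve$load),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_load_curve
#' @export
read_load_curve <- function(path) {
  tab <- utils::read.csv(path)
  structure(list(displacement = tab$displacement_mm, load = tab$load_n),
            class = "load_curve")
}
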