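## End-to-end orchestration: simulate a cohort, measure every specimen
## through the spectroscopy / morphometry / biomechanics stages, and run
## the statistical layer, with a manifest for reproducibility.

#' Derive a per-stage seed from a global seed
#'
#' Deterministic affine-modular map keeping every derived seed a valid
#' 32-bit integer, so each stage is independently reproducible from the
#' one run seed.
#'
#' @param seed global integer seed.
#' @param stage integer stage index (>= 0).
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stage) * 104729) %%
               2147483647)
}

#' Mean and sample SD summary of a cohort table
#'
#' @param cohort data.frame (a `cohort_sim` is accepted); all numeric
#'   columns are summarized with the sample (n - 1) standard deviation.
#' @return data.frame: `variable`, `mean`, `sd`, `n`.
#' @export
summarize_cohort <- function(cohort) {
  if (inherits(cohort, "cohort_sim")) cohort <- cohort$cohort
  num <- vapply(cohort, is.numeric, logical(1))
  if (nrow(cohort) < 2) stop("need at least 2 specimens for an SD")
  cols <- names(cohort)[num]
  data.frame(
    variable = cols,
    mean = vapply(cols, function(v) mean(cohort[[v]]), numeric(1)),
    sd = vapply(cols, function(v) stats::sd(cohort[[v]]), numeric(1)),
    n = nrow(cohort),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Default pipeline configuration
#'
#' Sizes are chosen so a full ten-specimen run (forty spectrum fits, ten
#' volumes, ten load curves, ten-way bootstrap regression) completes in
#' well under a minute on one core; every knob of the underlying stages is
#' exposed.
#'
#' @param n_specimens cohort size.
#' @param seed global seed; stage seeds derive from it via [derive_seed()].
#' @param snr spectrum amplitude SNR (Inf = noiseless).
#' @param n_points spectral points per echo.
#' @param volume_shape voxel counts of each specimen volume.
#' @param noise_sd_hu CT noise, HU.
#' @param threshold binarization threshold, mg/cm^3.
#' @param n_boot bootstrap samples per regression.
#' @param out_dir output directory (`NULL` = no files written).
#' @return list of class `run_config`.
#' @export
run_config <- function(n_specimens = 10, seed = 1L, snr = 50,
                       n_points = 2048, volume_shape = c(72, 72, 24),
                       noise_sd_hu = 0, threshold = 200, n_boot = 1000,
                       out_dir = NULL) {
  structure(list(n_specimens = n_specimens, seed = as.integer(seed),
                 snr = snr, n_points = n_points,
                 volume_shape = volume_shape, noise_sd_hu = noise_sd_hu,
                 threshold = threshold, n_boot = n_boot, out_dir = out_dir),
            class = "run_config")
}

## Build a specimen mask whose per-slice areas interpolate between the
## cohort row's min and max target so that min/mean areas are respected up
## to pixel rounding. Rectangular cross sections, slices along z.
specimen_mask_for_areas <- function(min_area, mean_area, dim_vol, voxel_size) {
  nz <- dim_vol[3]
  px_area <- voxel_size[1] * voxel_size[2] / 100  # cm^2 per pixel
  ## linear area profile from min to (2*mean - min) has the right mean
  targets <- seq(min_area, 2 * mean_area - min_area, length.out = nz)
  mask <- array(FALSE, dim_vol)
  for (k in seq_len(nz)) {
    n_px <- max(1L, round(targets[k] / px_area))
    w <- min(dim_vol[1], max(1L, round(sqrt(n_px))))
    h <- min(dim_vol[2], max(1L, ceiling(n_px / w)))
    x0 <- (dim_vol[1] - w) %/% 2L
    y0 <- (dim_vol[2] - h) %/% 2L
    mask[(x0 + 1):(x0 + w), (y0 + 1):(y0 + h), k] <- TRUE
  }
  mask
}

## Volume generator settings aimed at one cohort row: a one-voxel plate
## lattice whose period approximates the target BV/TV and a bone density
## chosen so the ROI mean density matches the target BMD.
volume_spec_for_row <- function(row, config, seed) {
  f_target <- max(0.05, min(0.9, row$bv_tv / 100))
  vx <- c(0.23, 0.23, 0.6)
  period <- max(2L, round(1 / f_target))
  f_lattice <- 1 / period
  marrow <- 50
  bone <- max(210, (row$bmd - marrow * (1 - f_lattice)) / f_lattice)
  volume_sim_spec(
    shape = config$volume_shape, voxel_size = vx,
    lattice = list(type = "plate", thickness = vx[1],
                   spacing = (period - 1) * vx[1], orientation = "x"),
    bone_density = bone, marrow_density = marrow,
    noise_sd_hu = config$noise_sd_hu, seed = seed)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages, in dependency order: (1) draw the specimen cohort; (2) per
#' specimen, simulate the four-echo spectrum set at the cohort row's fat
#' fraction and re-measure PDFF through phasing, constrained peak fitting
#' and T2 correction; (3) per specimen, simulate a lattice volume with an
#' embedded phantom and re-measure BMD, BV/TV, TbN and FD through
#' calibration, ROI placement, binarization, MIL and box counting, plus
#' cross-sectional areas from a synthetic specimen mask; (4) simulate the
#' load-displacement curve at the cohort row's failure load and re-detect
#' it; (5) summarize the measured table (mean +/- SD) and fit the pairwise
#' regression matrix with bootstrap validation.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_run`: `cohort_true` (generated rows),
#'   `cohort_measured` (pipeline measurements), `summary` (mean/SD table),
#'   `regressions` (pairwise matrix), `normality` (per-variable KS screen)
#'   and `manifest`. With `config$out_dir` set, CSVs and a JSON manifest
#'   are written there (also on failure, recording the failed stage).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("marrowmech")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list()
  )
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  finalize <- function(status, error = NULL) {
    manifest$finished <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    manifest$status <<- status
    if (!is.null(error)) manifest$error <<- error
    if (!is.null(out_dir)) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           force = TRUE)
    }
  }
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      finalize("failed", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(completed = TRUE)
    res
  }

  cohort_true <- run_stage("simulate_cohort", {
    generate_cohort(cohort_sim_spec(n_specimens = config$n_specimens,
                                    seed = derive_seed(config$seed, 1)))$cohort
  })

  measured <- run_stage("measure_specimens", {
    rows <- lapply(seq_len(nrow(cohort_true)), function(i) {
      row <- cohort_true[i, ]
      ## the Gaussian cohort model occasionally draws non-physical rows
      ## (e.g. negative loads three SDs below the mean); clamp them to
      ## physical floors before simulating the measurements
      row$min_area <- max(row$min_area, 1)
      row$mean_area <- max(row$mean_area, row$min_area)
      row$norm_fl <- max(row$norm_fl, 20)
      row$fl <- row$norm_fl * row$min_area
      ## spectroscopy
      sspec <- spectrum_sim_spec(
        pdff_true = min(max(row$fat_fraction / 100, 0.01), 0.99),
        snr = config$snr, n_points = config$n_points,
        seed = derive_seed(config$seed, 100 + i))
      pdff_fit <- fit_pdff(generate_spectrum(sspec))
      ## morphometry
      vol <- generate_volume(
        volume_spec_for_row(row, config, derive_seed(config$seed, 200 + i)))
      phantom_pairs <- data.frame(
        hu = vapply(vol$truth$phantom, function(b)
          mean(vol$hu[b$x[1]:b$x[2], b$y[1]:b$y[2], ]), numeric(1)),
        density = vapply(vol$truth$phantom, `[[`, numeric(1), "density"))
      lat <- vol$truth$lattice_region
      roi <- place_roi(dim(vol$hu), vol$voxel_size,
                       n_slices = min(20L, dim(vol$hu)[3]),
                       center = c(mean(lat$x), mean(lat$y)))
      morpho <- morphometry(vol$hu, vol$voxel_size, phantom_pairs,
                            threshold = config$threshold, roi = roi,
                            directions = "x")
      smask <- specimen_mask_for_areas(row$min_area, row$mean_area,
                                       c(124, 124, 20), vol$voxel_size)
      areas <- cross_sectional_areas(smask, vol$voxel_size)
      ## biomechanics
      curve <- generate_load_curve(row$fl, drop_fraction = 0.25,
                                   seed = derive_seed(config$seed, 300 + i))
      fl_det <- detect_failure_load(curve)
      data.frame(
        specimen_id = row$specimen_id,
        fat_fraction = 100 * pdff_fit$pdff,
        bmd = morpho$bmd, bv_tv = morpho$bv_tv, tbn = morpho$tbn,
        fd = morpho$fd,
        mean_area = areas$mean_area, min_area = areas$min_area,
        fl = fl_det$failure_load,
        norm_fl = normalize_fl(fl_det$failure_load, areas$min_area),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  summary_tbl <- run_stage("summarize", summarize_cohort(measured))
  normality <- run_stage("normality_screen", {
    vars <- c("fat_fraction", "bmd", "bv_tv", "tbn", "fd", "norm_fl")
    data.frame(
      variable = vars,
      ks_statistic = vapply(vars, function(v)
        ks_normality(measured[[v]])$statistic, numeric(1)),
      p = vapply(vars, function(v) ks_normality(measured[[v]])$p, numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  })
  regressions <- run_stage("regressions", {
    regression_table(measured, seed = derive_seed(config$seed, 2),
                     n_boot = config$n_boot)
  })

  if (!is.null(out_dir)) {
    utils::write.csv(cohort_true, file.path(out_dir, "cohort_true.csv"),
                     row.names = FALSE)
    utils::write.csv(measured, file.path(out_dir, "cohort_measured.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_tbl, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(regressions, file.path(out_dir, "regressions.csv"),
                     row.names = FALSE)
    manifest$outputs <- as.list(tools::md5sum(file.path(out_dir, c(
      "cohort_true.csv", "cohort_measured.csv", "summary.csv",
      "regressions.csv"))))
  }
  finalize("ok")
  structure(list(cohort_true = cohort_true, cohort_measured = measured,
                 summary = summary_tbl, normality = normality,
                 regressions = regressions, manifest = manifest),
            class = "pipeline_run")
}
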