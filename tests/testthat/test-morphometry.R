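test_that("phantom calibration recovers known affine maps", {
  id <- calibrate(data.frame(hu = c(0, 100), density = c(0, 100)))
  expect_equal(id$slope, 1)
  expect_equal(id$intercept, 0, tolerance = 1e-12)

  hu <- c(-40, 10, 150, 320)
  known <- calibrate(data.frame(hu = hu, density = 0.8 * hu - 5))
  expect_equal(known$slope, 0.8, tolerance = 1e-12)
  expect_equal(known$intercept, -5, tolerance = 1e-10)
  expect_equal(known$r_squared, 1)

  expect_error(calibrate(data.frame(hu = c(50, 50), density = c(0, 100))),
               "singular")
  expect_error(calibrate(data.frame(hu = 1, density = 1)), "at least two")
})

test_that("applying a calibration is an element-wise affine map", {
  vol <- array(250, c(4, 4, 2))
  cal <- calibrate(data.frame(hu = c(0, 100), density = c(-5, 75)))
  expect_equal(apply_calibration(vol, cal),
               array(0.8 * 250 - 5, c(4, 4, 2)), tolerance = 1e-10)
  id <- calibrate(data.frame(hu = c(0, 1), density = c(0, 1)))
  expect_equal(apply_calibration(vol, id), vol, tolerance = 1e-12)
})

test_that("ROI placement rounds 12 mm to 52 voxels and selects central slices", {
  roi <- place_roi(c(100, 100, 40), c(0.23, 0.23, 0.6))
  expect_length(roi$x, 52)   # 12 / 0.23 = 52.17
  expect_length(roi$z, 20)
  roi_all <- place_roi(c(100, 100, 20), c(0.23, 0.23, 0.6), n_slices = 20)
  expect_identical(roi_all$z, 1:20)
  expect_error(place_roi(c(100, 100, 10), c(0.23, 0.23, 0.6), n_slices = 20),
               "axis z")
  expect_error(place_roi(c(30, 100, 40), c(0.23, 0.23, 0.6)), "axis x")
  # ties round toward the larger window: 11.5 mm at 1 mm voxels -> 12
  expect_length(place_roi(c(40, 40, 5), c(1, 1, 1), extent_mm = 11.5,
                          n_slices = 3)$x, 12)
})

test_that("mean BMD matches direct averaging", {
  vol <- array(121.5, c(60, 60, 25))
  roi <- place_roi(dim(vol), c(0.23, 0.23, 0.6), n_slices = 20)
  expect_equal(mean_bmd(vol, roi), 121.5)

  vol2 <- array(c(0, 200), c(10, 10, 2))
  expect_equal(mean_bmd(vol2), 100)

  set.seed(4)
  vol3 <- array(runif(8^3, 0, 400), c(8, 8, 8))
  s <- 0
  for (v in vol3) s <- s + v
  expect_equal(mean_bmd(vol3), s / length(vol3), tolerance = 1e-12)
})

test_that("binarization is inclusive at the threshold", {
  vol <- array(c(199.999, 200, 200.001, 120), c(2, 2, 1))
  mask <- binarize(vol)
  expect_identical(as.vector(mask), c(FALSE, TRUE, TRUE, FALSE))
  expect_false(any(binarize(array(120, c(4, 4, 2)))))
})

test_that("BV/TV equals the exhaustive voxel count", {
  expect_equal(bv_tv(array(TRUE, c(4, 4, 4))), 100)
  m <- random_mask(c(9, 7, 5), 0.3, seed = 8)
  expect_equal(bv_tv(m), oracle_bvtv(m))
  expect_error(bv_tv(logical(0)), "empty")
})

test_that("MIL on the plate lattice matches the closed form", {
  v <- generate_volume(volume_sim_spec(shape = c(64, 64, 32)))
  lat <- v$truth$lattice_region
  mask <- v$truth$mask
  res <- mil_tbn(mask, v$voxel_size, directions = "x")
  expect_equal(unname(res$mil[["x"]]), 0.23, tolerance = 1e-12)
  expect_equal(res$tbn, 0.25 / 0.23, tolerance = 1e-12)
  # plate-parallel direction: whole rows are bone, no transitions; MIL
  # degrades to the full line length
  res_y <- mil_tbn(mask, v$voxel_size, directions = "y")
  expect_equal(unname(res_y$mil[["y"]]),
               dim(mask)[2] * v$voxel_size[2], tolerance = 1e-12)
  expect_equal(res_y$counts$y$transitions, 0)
})

test_that("MIL agrees exactly with the brute-force line walk", {
  for (seed in 1:5) {
    m <- random_mask(c(11, 9, 7), 0.35, seed = seed)
    res <- mil_tbn(m, c(0.23, 0.23, 0.6))
    for (ax in 1:3) {
      o <- oracle_mil_direction(m, c(0.23, 0.23, 0.6), ax)
      d <- c("x", "y", "z")[ax]
      expect_equal(unname(res$mil[[d]]), o$mil)
      expect_equal(res$counts[[d]]$transitions, o$transitions)
      expect_equal(res$counts[[d]]$bone_length, o$bone_length)
    }
  }
})

test_that("MIL rejects single-phase volumes", {
  expect_error(mil_tbn(array(TRUE, c(4, 4, 4)), c(1, 1, 1)), "entirely bone")
  expect_error(mil_tbn(array(FALSE, c(4, 4, 4)), c(1, 1, 1)),
               "entirely marrow")
})

test_that("box-counting FD hits the filled-plane and line anchors", {
  filled <- fractal_dimension(array(TRUE, c(64, 64, 1)))
  expect_equal(filled$fd, 2, tolerance = 1e-9)
  line <- matrix(FALSE, 64, 64)
  line[32, ] <- TRUE
  expect_equal(fractal_dimension(list(line))$fd, 1, tolerance = 1e-9)
})

test_that("box counts equal the exhaustive enumeration on random slices", {
  for (seed in 1:5) {
    set.seed(seed)
    slice <- matrix(runif(48 * 40) < 0.2, 48, 40)
    sizes <- c(2, 4, 8, 16)
    res <- fractal_dimension(list(slice), box_sizes = sizes)
    for (k in seq_along(sizes)) {
      expect_equal(res$counts[1, k], oracle_box_count(slice, sizes[k]))
    }
  }
})

test_that("FD guards degenerate inputs", {
  expect_error(fractal_dimension(list(matrix(TRUE, 8, 8)),
                                 box_sizes = c(2, 4)), "three box sizes")
  expect_error(fractal_dimension(list(matrix(FALSE, 8, 8))), "zero bone")
  expect_warning(
    fractal_dimension(list(matrix(TRUE, 16, 16), matrix(FALSE, 16, 16)),
                      box_sizes = c(2, 4, 8)), "excluded")
})

test_that("cross-sectional areas follow pixel counting", {
  prism <- array(FALSE, c(60, 60, 5))
  prism[1:50, 1:50, ] <- TRUE
  res <- cross_sectional_areas(prism, c(0.23, 0.23, 0.6))
  expect_equal(res$mean_area, 50 * 50 * 0.23^2 / 100, tolerance = 1e-12)
  expect_equal(res$min_area, res$mean_area)

  # stepped specimen: slices of 4.9 and 9.7 cm^2 at 1 mm pixels
  stepped <- array(FALSE, c(60, 60, 2))
  stepped[1:10, 1:49, 1] <- TRUE   # 490 px = 4.9 cm^2
  stepped[1:20, 1:40, 2] <- TRUE   # 800 px
  stepped[21:30, 1:17, 2] <- TRUE  # +170 px = 9.7 cm^2
  res2 <- cross_sectional_areas(stepped, c(1, 1, 1))
  expect_equal(res2$min_area, 4.9)
  expect_equal(res2$mean_area, 7.3)

  m <- random_mask(c(12, 10, 6), 0.3, seed = 2)
  o <- oracle_areas(m, c(0.23, 0.23, 0.6))
  res3 <- cross_sectional_areas(m, c(0.23, 0.23, 0.6))
  expect_equal(res3$mean_area, o$mean_area)
  expect_equal(res3$min_area, o$min_area)

  expect_error(cross_sectional_areas(array(FALSE, c(4, 4, 2)), c(1, 1, 1)),
               "empty")
})

test_that("BV/TV is non-increasing in the threshold", {
  set.seed(10)
  dens <- array(runif(16^3, 0, 400), c(16, 16, 16))
  bv <- vapply(seq(0, 400, by = 40),
               function(th) bv_tv(binarize(dens, th)), numeric(1))
  expect_true(all(diff(bv) <= 0))
})

test_that("axis MILs agree for an isotropic random medium", {
  # average over seeds; a fine-grained isotropic field has no preferred axis
  mils <- matrix(NA_real_, 30, 3)
  for (s in 1:30) {
    m <- random_mask(c(24, 24, 24), 0.4, seed = 100 + s)
    mils[s, ] <- mil_tbn(m, c(1, 1, 1))$mil
  }
  mm <- colMeans(mils)
  expect_lt(max(mm) / min(mm) - 1, 0.05)
})

test_that("morphometry is invariant to voxel-size refinement on lattices", {
  coarse <- generate_volume(volume_sim_spec(shape = c(64, 64, 32)))
  fine <- generate_volume(volume_sim_spec(
    shape = c(128, 128, 64), voxel_size = c(0.115, 0.115, 0.3),
    lattice = list(type = "plate", thickness = 0.23, spacing = 0.69,
                   orientation = "x")))
  expect_equal(fine$truth$bv_tv, coarse$truth$bv_tv)
  expect_equal(unname(fine$truth$mil["x"]), unname(coarse$truth$mil["x"]),
               tolerance = 1e-12)
  mc <- mil_tbn(coarse$truth$mask, coarse$voxel_size, "x")
  mf <- mil_tbn(fine$truth$mask, fine$voxel_size, "x")
  expect_equal(mf$mil[["x"]], mc$mil[["x"]], tolerance = 1e-12)
  expect_equal(mf$tbn, mc$tbn, tolerance = 1e-12)
})
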