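test_that("the generated softening curve returns its true failure load", {
  curve <- generate_load_curve(2580, drop_fraction = 0.2)
  res <- detect_failure_load(curve)
  expect_true(res$detected)
  expect_equal(res$failure_load, 2580)
  expect_gt(res$drop_observed, 0.10)
  # normalized against the cohort-scale minimum area
  expect_equal(normalize_fl(798 * 6.5, 6.5), 798)
})

test_that("a drop of at most 10% never qualifies (strict rule)", {
  curve <- list(displacement = 0:3, load = c(0, 1000, 900, 950))
  expect_false(detect_failure_load(curve)$detected)
  curve$load[3] <- 899.999
  expect_true(detect_failure_load(curve)$detected)
  # generator fixture with a small drop
  expect_false(detect_failure_load(generate_load_curve(400, 0.05))$detected)
})

test_that("the first qualifying peak wins over larger later peaks", {
  d <- seq(0, 10, length.out = 11)
  load <- c(0, 500, 1000, 850, 900, 1200, 1500, 700, 1400, 600, 650)
  res <- detect_failure_load(list(displacement = d, load = load))
  expect_true(res$detected)
  expect_equal(res$failure_load, 1000)
  expect_equal(res$failure_index, 3L)
})

test_that("detection is scale-equivariant and ignores post-failure samples", {
  curve <- generate_load_curve(1234, drop_fraction = 0.3, n_points = 80)
  res <- detect_failure_load(curve)
  scaled <- list(displacement = curve$displacement, load = curve$load * 4.5)
  res_s <- detect_failure_load(scaled)
  expect_equal(res_s$failure_load, 4.5 * res$failure_load)
  expect_equal(res_s$failure_index, res$failure_index)

  extended <- list(
    displacement = c(curve$displacement,
                     max(curve$displacement) + (1:20) / 10),
    load = c(curve$load, runif(20, 0, 3000)))
  res_e <- detect_failure_load(extended)
  expect_equal(res_e$failure_load, res$failure_load)
  expect_equal(res_e$failure_index, res$failure_index)
})

test_that("detection agrees with the all-maxima oracle on random curves", {
  for (seed in 1:100) {
    curve <- random_load_curve(seed)
    res <- detect_failure_load(curve)
    o <- oracle_failure(curve$load)
    expect_equal(res$detected, o$detected, info = paste("seed", seed))
    if (o$detected) {
      expect_equal(res$failure_load, o$failure_load,
                   info = paste("seed", seed))
      expect_equal(res$failure_index, o$failure_index,
                   info = paste("seed", seed))
    }
  }
})

test_that("input validation catches malformed curves and windows", {
  good <- generate_load_curve(1000, 0.2)
  expect_error(detect_failure_load(
    list(displacement = c(0, 2, 1), load = c(0, 5, 3))), "non-decreasing")
  expect_error(detect_failure_load(good, smoothing_window = 2), "odd")
  expect_error(normalize_fl(500, 0), "positive")
  expect_error(normalize_fl(500, -2), "positive")
})

test_that("normalization inverts exactly", {
  expect_equal(normalize_fl(400, 2), 200)
  fl <- 1834.7
  expect_equal(normalize_fl(fl, 5.2) * 5.2, fl, tolerance = 1e-12)
})

test_that("smoothing suppresses jitter peaks but reports raw load", {
  base <- generate_load_curve(2000, 0.25, n_points = 100)
  jitter <- base
  set.seed(42)
  jitter$load <- jitter$load + rnorm(100, 0, 15)
  res <- detect_failure_load(jitter, smoothing_window = 5)
  expect_true(res$detected)
  # reported at the unsmoothed sample value near the true peak
  expect_lt(abs(res$failure_load - 2000) / 2000, 0.05)
})
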