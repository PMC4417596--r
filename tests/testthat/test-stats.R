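test_that("normality screen flags bimodal data and guards degeneracy", {
  expect_error(ks_normality(rep(5, 20)), "zero variance")
  set.seed(1)
  bimodal <- c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1))
  expect_lt(ks_normality(bimodal)$p, 0.05)
  normal <- rnorm(200)
  res <- ks_normality(normal)
  expect_true(res$statistic >= 0 && res$statistic <= 1)
  # SPSS-style uncorrected variant runs and gives a (larger) p
  expect_gte(ks_normality(normal, lilliefors = FALSE)$p, res$p)
})

test_that("a perfect linear relation is fitted exactly", {
  x <- 1:5
  fit <- linreg(x, 2 * x + 1)
  expect_equal(fit$B, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r, 1)
  expect_equal(fit$se_B, 0)
  expect_equal(fit$p, 0)
})

test_that("independent variables show near-zero correlation at large n", {
  set.seed(3)
  fit <- linreg(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(fit$r), 0.05)
})

test_that("closed-form OLS matches the design-matrix oracle and lm", {
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(12)
    y <- 1.5 * x + rnorm(12)
    fit <- linreg(x, y)
    o <- oracle_ols(x, y)
    expect_equal(fit$B, o$B, tolerance = 1e-10)
    expect_equal(fit$se_B, o$se_B, tolerance = 1e-10)
    expect_equal(fit$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(fit$p, o$p, tolerance = 1e-10)
    expect_equal(fit$r, o$r, tolerance = 1e-12)
    lmfit <- summary(lm(y ~ x))
    expect_equal(fit$B, unname(lmfit$coefficients[2, 1]), tolerance = 1e-12)
    expect_equal(fit$se_B, unname(lmfit$coefficients[2, 2]),
                 tolerance = 1e-12)
    expect_equal(fit$p, unname(lmfit$coefficients[2, 4]), tolerance = 1e-12)
  }
})

test_that("r^2 equals the squared Pearson correlation", {
  set.seed(12)
  x <- rnorm(30); y <- -0.7 * x + rnorm(30)
  fit <- linreg(x, y)
  expect_equal(fit$r^2, cor(x, y)^2, tolerance = 1e-12)
  expect_equal(sign(fit$r), sign(fit$B))
})

test_that("correlation is symmetric while slopes are not", {
  set.seed(5)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20, sd = 2)
  expect_equal(linreg(x, y)$r, linreg(y, x)$r, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(linreg(x, y)$B, linreg(y, x)$B)))
})

test_that("regression guards degenerate inputs", {
  expect_error(linreg(rep(1, 5), rnorm(5)), "constant x")
  expect_error(linreg(1:2, 1:2), "at least 3")
  expect_error(linreg(c(1, 2, NA), c(1, 2, 3)), "non-finite")
})

test_that("a perfect fit bootstrap collapses to zero SE and the p floor", {
  x <- 1:10
  res <- bootstrap_regression(x, 2 * x, n_boot = 500, seed = 4)
  expect_equal(res$se_B_boot, 0)
  expect_equal(res$p_boot, 2 / 500)
  expect_equal(unname(res$slope_quantiles), rep(2, 5))
})

test_that("bootstrap results are bit-identical under a fixed seed", {
  set.seed(30)
  x <- rnorm(15); y <- x + rnorm(15)
  a <- bootstrap_regression(x, y, seed = 123)
  b <- bootstrap_regression(x, y, seed = 123)
  expect_identical(a, b)
  expect_error(bootstrap_regression(x, y, n_boot = 50), "at least 100")
})

test_that("bootstrap SE tracks the analytic OLS SE", {
  # moderate n, averaged over repeated datasets
  set.seed(77)
  ratios <- replicate(40, {
    x <- rnorm(200)
    y <- 1 + 0.5 * x + rnorm(200)
    bootstrap_regression(x, y, n_boot = 400,
                         seed = sample.int(1e6, 1))$se_B_boot /
      linreg(x, y)$se_B
  })
  expect_lt(abs(mean(ratios) - 1), 0.15)
})

test_that("the normal-approximation bootstrap p is available", {
  set.seed(9)
  x <- rnorm(20); y <- 2 * x + rnorm(20)
  res <- bootstrap_regression(x, y, seed = 2, p_method = "normal")
  expect_true(res$p_boot >= 0 && res$p_boot <= 1)
  expect_identical(res$p_method, "normal")
})

test_that("the pairwise regression matrix covers both model families", {
  cs <- generate_cohort(cohort_sim_spec(seed = 14))
  tab <- regression_table(cs, seed = 3, n_boot = 200)
  expect_equal(nrow(tab), 10)
  expect_setequal(unique(tab$x), c("fat_fraction", "norm_fl"))
  expect_equal(sum(tab$x == "fat_fraction"), 5)
  expect_true(all(abs(tab$r) <= 1))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(tab$se_B_boot >= 0))
  expect_true(all(tab$n == 10))
  # r symmetric between the two orderings of the same pair
  r1 <- tab$r[tab$x == "fat_fraction" & tab$y == "norm_fl"]
  r2 <- tab$r[tab$x == "norm_fl" & tab$y == "fat_fraction"]
  expect_equal(r1, r2, tolerance = 1e-12)
  # deterministic given the seed
  tab2 <- regression_table(cs, seed = 3, n_boot = 200)
  expect_identical(tab, tab2)
  expect_error(regression_table(cs$cohort[, 1:3], seed = 1), "missing columns")
})
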