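## Statistical layer: normality screening, pairwise ordinary least squares,
## and bootstrap validation of the regression slopes.

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of the values against a normal distribution with
#' mean and SD estimated from the sample. Because the null parameters are
#' estimated, the default p-value uses the Lilliefors correction; the
#' uncorrected asymptotic KS p (as in some legacy statistics packages) is
#' available with `lilliefors = FALSE`.
#'
#' @param values numeric sample, n >= 5, positive variance.
#' @param lilliefors use the estimation-adjusted null (default `TRUE`).
#' @return list: `statistic` (supremum CDF distance) and `p`.
#' @export
ks_normality <- function(values, lilliefors = TRUE) {
  values <- as.numeric(values)
  if (length(values) < 5) stop("need at least 5 values")
  if (stats::sd(values) == 0) stop("zero variance: normality test undefined")
  if (lilliefors) {
    t <- nortest::lillie.test(values)
  } else {
    t <- suppressWarnings(
      stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  }
  list(statistic = unname(t$statistic), p = unname(t$p.value))
}

#' Simple linear regression with Pearson correlation
#'
#' Ordinary least squares of `y` on `x`, reported as the slope coefficient
#' `B`, its standard error, the Pearson correlation `r` (which carries the
#' sign of `B`), and the two-sided p-value from the t distribution with
#' n - 2 degrees of freedom. Computed in closed form.
#'
#' @param x,y numeric vectors of equal length n >= 3; `x` must vary.
#' @return list of class `regression_result`: `B`, `se_B`, `intercept`,
#'   `r`, `p`, `n`.
#' @export
linreg <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("missing or non-finite values")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("constant x: regression undefined")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  se_b <- sqrt(rss / (n - 2) / sxx)
  syy <- sum((y - mean(y))^2)
  r <- if (syy == 0) 0 else sxy / sqrt(sxx * syy)
  tstat <- if (se_b == 0) sign(b) * Inf else b / se_b
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(B = b, se_B = se_b, intercept = a, r = r, p = p, n = n),
            class = "regression_result")
}

#' Bootstrap validation of a regression slope
#'
#' Case (pairwise) resampling with replacement: `n_boot` replicates of
#' size n, refitting the OLS slope on each. The bootstrap standard error
#' is the SD of the replicate slopes. The default bootstrap p-value is
#' twice the smaller sign-crossing proportion of the replicate slopes,
#' floored at `2 / n_boot`; `p_method = "normal"` instead refers
#' `B / se_boot` to the standard normal. Replicates with constant `x`
#' (impossible slope) are redrawn and counted.
#'
#' @param x,y numeric vectors, n >= 3.
#' @param n_boot number of bootstrap samples (>= 100; default 1000).
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @param p_method "sign" (default) or "normal".
#' @return list of class `bootstrap_result`: `se_B_boot`, `p_boot`,
#'   `n_boot`, `seed`, `slope_quantiles` (2.5/25/50/75/97.5%), and
#'   `n_degenerate_redrawn`.
#' @export
bootstrap_regression <- function(x, y, n_boot = 1000, seed = 1L,
                                 p_method = c("sign", "normal")) {
  p_method <- match.arg(p_method)
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (n_boot < 100) stop("n_boot must be at least 100")
  base_fit <- linreg(x, y)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  slopes <- numeric(n_boot)
  n_degen <- 0L
  xc <- x; yc <- y
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- xc[idx]
      if (stats::var(xb) > 0) break
      n_degen <- n_degen + 1L
    }
    yb <- yc[idx]
    mx <- mean(xb)
    slopes[b] <- sum((xb - mx) * (yb - mean(yb))) / sum((xb - mx)^2)
  }
  se_boot <- stats::sd(slopes)
  p_boot <- if (p_method == "sign") {
    max(2 * min(mean(slopes <= 0), mean(slopes >= 0)), 2 / n_boot)
  } else {
    if (se_boot == 0) 2 / n_boot
    else 2 * stats::pnorm(-abs(base_fit$B / se_boot))
  }
  structure(list(
    se_B_boot = se_boot, p_boot = p_boot, n_boot = as.integer(n_boot),
    seed = as.integer(seed),
    slope_quantiles = stats::quantile(slopes, c(0.025, 0.25, 0.5, 0.75, 0.975)),
    n_degenerate_redrawn = n_degen,
    p_method = p_method
  ), class = "bootstrap_result")
}

#' Pairwise regression matrix over a specimen cohort
#'
#' Computes the two families of pairwise models that summarize the study:
#' (i) fat fraction against normalized failure load, BMD, BV/TV, TbN and
#' FD, and (ii) normalized failure load against fat fraction, BMD, BV/TV,
#' TbN and FD. Each model carries the plain OLS results and the bootstrap
#' validation.
#'
#' @param cohort data.frame with columns `fat_fraction`, `bmd`, `bv_tv`,
#'   `tbn`, `fd`, `norm_fl` (a `cohort_sim` is accepted).
#' @param seed integer; per-model bootstrap seeds are derived from it
#'   deterministically.
#' @param n_boot bootstrap samples per model.
#' @return data.frame, one row per (x, y) pair: `x`, `y`, `n`, `B`,
#'   `se_B`, `r`, `p`, `se_B_boot`, `p_boot`, `n_boot`, `seed`.
#' @export
regression_table <- function(cohort, seed = 1L, n_boot = 1000) {
  if (inherits(cohort, "cohort_sim")) cohort <- cohort$cohort
  predictors <- list(
    fat_fraction = c("norm_fl", "bmd", "bv_tv", "tbn", "fd"),
    norm_fl = c("fat_fraction", "bmd", "bv_tv", "tbn", "fd")
  )
  missing_cols <- setdiff(unique(c(names(predictors), unlist(predictors))),
                          names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  rows <- list()
  k <- 0L
  for (xvar in names(predictors)) {
    for (yvar in predictors[[xvar]]) {
      k <- k + 1L
      fit <- linreg(cohort[[xvar]], cohort[[yvar]])
      bt <- bootstrap_regression(cohort[[xvar]], cohort[[yvar]],
                                 n_boot = n_boot,
                                 seed = derive_seed(seed, k))
      rows[[k]] <- data.frame(
        x = xvar, y = yvar, n = fit$n, B = fit$B, se_B = fit$se_B,
        r = fit$r, p = fit$p, se_B_boot = bt$se_B_boot, p_boot = bt$p_boot,
        n_boot = bt$n_boot, seed = as.integer(seed),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
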