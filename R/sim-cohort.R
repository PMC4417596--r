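## Correlated specimen cohorts drawn from a multivariate normal with the
## study's variable set: fat fraction, BMD, trabecular microstructure,
## normalized failure load and cross-sectional areas.

#' Default cohort distribution parameters
#'
#' Means and SDs of the measured variables in a ten-vertebra thoracic
#' cohort (fat fraction 32 +/- 5 %, BMD 121.5 +/- 34.3 mg/cm^3, BV/TV
#' 38.8 +/- 10.8 %, TbN 1.13 +/- 0.11 mm^-1, FD 1.57 +/- 0.07, normalized
#' failure load 442 +/- 251 N/cm^2, mean cross-sectional area
#' 6.5 +/- 1.5 cm^2; the minimum area, 5.9 +/- 1.4 cm^2, sits slightly
#' below the mean area). The correlation structure carries the reported
#' pairwise pattern: fat fraction correlates negatively with normalized
#' failure load (-0.77), BMD (-0.72), BV/TV (-0.64), TbN (-0.62) and FD
#' (-0.36); normalized failure load correlates strongly with BMD (0.90),
#' BV/TV (0.88), TbN (0.89) and FD (0.83). Correlations among the density /
#' microstructure variables themselves, and between the two area measures,
#' are not reported for this cohort and are set to values typical of
#' trabecular bone, adjusted once to keep the matrix positive definite.
#'
#' @return list with `means`, `sds` (named vectors over the eight
#'   variables) and `correlation` (8 x 8 symmetric positive-definite
#'   matrix).
#' @export
default_cohort_params <- function() {
  vars <- c("fat_fraction", "bmd", "bv_tv", "tbn", "fd",
            "norm_fl", "mean_area", "min_area")
  means <- c(fat_fraction = 32, bmd = 121.5, bv_tv = 38.8, tbn = 1.13,
             fd = 1.57, norm_fl = 442, mean_area = 6.5, min_area = 5.9)
  sds <- c(fat_fraction = 5, bmd = 34.3, bv_tv = 10.8, tbn = 0.11,
           fd = 0.07, norm_fl = 251, mean_area = 1.5, min_area = 1.4)
  r <- diag(8)
  dimnames(r) <- list(vars, vars)
  set_r <- function(a, b, v) {
    r[a, b] <<- v; r[b, a] <<- v
  }
  set_r("fat_fraction", "norm_fl", -0.77)
  set_r("fat_fraction", "bmd", -0.72)
  set_r("fat_fraction", "bv_tv", -0.64)
  set_r("fat_fraction", "tbn", -0.62)
  set_r("fat_fraction", "fd", -0.36)
  set_r("norm_fl", "bmd", 0.90)
  set_r("norm_fl", "bv_tv", 0.88)
  set_r("norm_fl", "tbn", 0.89)
  set_r("norm_fl", "fd", 0.83)
  ## unreported structure-structure correlations: typical trabecular values
  set_r("bmd", "bv_tv", 0.85)
  set_r("bmd", "tbn", 0.80)
  set_r("bmd", "fd", 0.70)
  set_r("bv_tv", "tbn", 0.85)
  set_r("bv_tv", "fd", 0.72)
  set_r("tbn", "fd", 0.75)
  set_r("mean_area", "min_area", 0.90)
  list(means = means, sds = sds, correlation = r)
}

#' Specification for a synthetic specimen cohort
#'
#' @param n_specimens number of specimens (>= 3).
#' @param means,sds named numeric vectors over the cohort variables
#'   (defaults: [default_cohort_params()]).
#' @param correlation symmetric positive-semidefinite correlation matrix
#'   with unit diagonal, matching `means` in order.
#' @param seed integer seed.
#' @return object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_specimens = 10,
                            means = default_cohort_params()$means,
                            sds = default_cohort_params()$sds,
                            correlation = default_cohort_params()$correlation,
                            seed = 1L) {
  stopifnot(n_specimens >= 3, length(means) == length(sds),
            all(sds >= 0), nrow(correlation) == length(means),
            ncol(correlation) == length(means))
  if (max(abs(correlation - t(correlation))) > 1e-12) {
    stop("correlation matrix must be symmetric")
  }
  if (max(abs(diag(correlation) - 1)) > 1e-12) {
    stop("correlation matrix must have unit diagonal")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf(
      "correlation matrix is not positive semidefinite (smallest eigenvalue %.3g)",
      min(ev)))
  }
  structure(list(n_specimens = as.integer(n_specimens), means = means,
                 sds = sds, correlation = correlation,
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

#' Generate a correlated specimen cohort
#'
#' Draws `n_specimens` rows from a multivariate normal with the given
#' means, SDs and correlation matrix (eigendecomposition transform, so
#' positive-semidefinite matrices and zero SDs are handled exactly), and
#' derives the absolute failure load as `fl = norm_fl * min_area`.
#'
#' @param spec a [cohort_sim_spec()].
#' @return list of class `cohort_sim`: `cohort` (data.frame with
#'   `specimen_id`, the eight generated variables and derived `fl`) and
#'   `params` (the generating spec).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  p <- length(spec$means)
  eg <- eigen(spec$correlation, symmetric = TRUE)
  transform <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), p)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  z <- matrix(stats::rnorm(spec$n_specimens * p), spec$n_specimens, p)
  x <- z %*% t(transform)
  x <- sweep(x, 2, spec$sds, `*`)
  x <- sweep(x, 2, spec$means, `+`)
  colnames(x) <- names(spec$means)
  cohort <- data.frame(specimen_id = sprintf("S%02d", seq_len(spec$n_specimens)),
                       x, stringsAsFactors = FALSE)
  if (all(c("norm_fl", "min_area") %in% names(cohort))) {
    cohort$fl <- cohort$norm_fl * cohort$min_area
  }
  structure(list(cohort = cohort, params = spec), class = "cohort_sim")
}
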