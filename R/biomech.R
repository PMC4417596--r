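## Failure-load extraction from uniaxial compression load-displacement
## curves: the first local load maximum followed by a drop of more than 10%
## before the load recovers past that maximum.

#' Generate a synthetic load-displacement curve
#'
#' Piecewise-linear softening curve: a monotone rise to the true failure
#' load, a post-yield drop of `drop_fraction`, then a secondary rise to
#' `rebound * fl_true`. The grid contains the peak exactly, so the
#' failure-load rule applied to the noiseless curve returns `fl_true`
#' exactly.
#'
#' @param fl_true true failure load, N (> 0).
#' @param drop_fraction post-peak drop as a fraction of the peak, in (0, 1).
#' @param n_points number of samples (>= 10).
#' @param rebound terminal load as a fraction of `fl_true` (may exceed 1
#'   to build curves whose later structure overtakes the first peak).
#' @param noise_sd load noise SD, N (default 0).
#' @param seed noise seed.
#' @return list of class `load_curve`: `displacement` (mm, strictly
#'   increasing), `load` (N), and `fl_true`.
#' @export
generate_load_curve <- function(fl_true, drop_fraction, n_points = 200,
                                rebound = 0.95, noise_sd = 0, seed = 1L) {
  stopifnot(fl_true > 0, drop_fraction > 0, drop_fraction < 1,
            n_points >= 10, noise_sd >= 0)
  n_rise <- max(3L, round(0.45 * n_points))
  n_drop <- max(2L, round(0.2 * n_points))
  n_tail <- n_points - n_rise - n_drop
  trough <- fl_true * (1 - drop_fraction)
  ## slightly convex rise, as real vertebrae stiffen after toe-in
  rise <- fl_true * (seq(0, 1, length.out = n_rise))^1.3
  drop <- seq(fl_true, trough, length.out = n_drop + 1)[-1]
  tail <- if (n_tail > 0) {
    seq(trough, rebound * fl_true, length.out = n_tail + 1)[-1]
  } else numeric(0)
  load <- c(rise, drop, tail)
  if (noise_sd > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(as.integer(seed))
    ## keep the generating peak exact: no noise at the peak sample
    noise <- stats::rnorm(length(load), 0, noise_sd)
    noise[n_rise] <- 0
    load <- load + noise
  }
  structure(list(displacement = seq(0, 3, length.out = n_points),
                 load = load, fl_true = fl_true),
            class = "load_curve")
}

## Indices of (strict-rise, plateau-tolerant) local maxima, interior only.
local_maxima <- function(y) {
  n <- length(y)
  out <- integer(0)
  i <- 2L
  while (i < n) {
    if (y[i] > y[i - 1]) {
      ## extend over any plateau
      j <- i
      while (j < n && y[j + 1] == y[j]) j <- j + 1L
      if (j < n && y[j + 1] < y[j]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Detect the failure load of a load-displacement curve
#'
#' Scans local load maxima in order of displacement. A maximum `M`
#' qualifies as the failure point if the minimum load after it — up to the
#' sample where the load first exceeds `M` again, or the end of the curve —
#' falls strictly below `0.9 * M` (a drop of more than 10%). The first
#' qualifying maximum is returned at its unsmoothed load value.
#'
#' @param curve a `load_curve`, or any list with numeric `displacement`
#'   (non-decreasing) and `load` of equal length >= 3.
#' @param smoothing_window odd integer; width of an optional centred
#'   moving average applied before peak scanning (1 = no smoothing,
#'   the default).
#' @return list of class `failure_result`: `detected` (logical),
#'   `failure_load` (N, `NA` if none), `failure_index`, and
#'   `drop_observed` (fraction of the peak).
#' @export
detect_failure_load <- function(curve, smoothing_window = 1) {
  d <- curve$displacement; load <- curve$load
  stopifnot(length(d) == length(load), length(load) >= 3,
            all(is.finite(load)))
  if (any(diff(d) < 0)) stop("displacement must be non-decreasing")
  if (smoothing_window %% 2 != 1 || smoothing_window < 1) {
    stop("smoothing_window must be odd and >= 1")
  }
  y <- if (smoothing_window > 1) {
    as.numeric(stats::filter(load, rep(1 / smoothing_window,
                                       smoothing_window), sides = 2))
  } else load
  ## centred filter leaves NAs at the edges; fall back to raw values there
  y[is.na(y)] <- load[is.na(y)]

  for (i in local_maxima(y)) {
    m <- y[i]
    after <- y[(i + 1):length(y)]
    over <- which(after > m)
    window <- if (length(over) > 0 && over[1] == 1) numeric(0)
              else if (length(over) > 0) after[seq_len(over[1] - 1)]
              else after
    if (length(window) > 0 && min(window) < 0.9 * m) {
      return(structure(list(
        detected = TRUE,
        failure_load = load[i],
        failure_index = i,
        drop_observed = 1 - min(window) / m
      ), class = "failure_result"))
    }
  }
  structure(list(detected = FALSE, failure_load = NA_real_,
                 failure_index = NA_integer_, drop_observed = NA_real_),
            class = "failure_result")
}

#' Normalize failure load by the minimum cross-sectional area
#'
#' @param failure_load N.
#' @param min_area minimum transverse cross-sectional area, cm^2 (> 0).
#' @return normalized failure load, N/cm^2.
#' @export
normalize_fl <- function(failure_load, min_area) {
  if (!is.finite(min_area) || min_area <= 0) {
    stop("min_area must be positive")
  }
  failure_load / min_area
}
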