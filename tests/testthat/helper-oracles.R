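# Independent brute-force oracles. These deliberately use naive loops /
# run-length walks, not the package's vectorized shift-and-count code.

random_mask <- function(dim3, p = 0.4, seed = 1) {
  set.seed(seed)
  array(runif(prod(dim3)) < p, dim3)
}

oracle_bvtv <- function(mask) {
  n_bone <- 0L
  for (v in mask) if (v) n_bone <- n_bone + 1L
  100 * n_bone / length(mask)
}

# Walk every line along `axis`, accumulating bone voxels and strict
# marrow-to-bone entries, via run-length encoding of each line.
oracle_mil_direction <- function(mask, voxel_size, axis) {
  d <- dim(mask)
  perp <- setdiff(1:3, axis)
  bone <- 0L; trans <- 0L; lines_with_bone <- 0L
  for (i in seq_len(d[perp[1]])) {
    for (j in seq_len(d[perp[2]])) {
      line <- switch(axis,
                     mask[, i, j], mask[i, , j], mask[i, j, ])
      r <- rle(line)
      bone <- bone + sum(r$lengths[r$values])
      # entries: bone runs preceded by a marrow run
      vals <- r$values
      trans <- trans + sum(vals[-1] & !vals[-length(vals)])
      if (any(line)) lines_with_bone <- lines_with_bone + 1L
    }
  }
  bone_len <- bone * voxel_size[axis]
  mil <- if (trans > 0) bone_len / trans
         else if (lines_with_bone > 0) bone_len / lines_with_bone
         else NA_real_
  list(bone_length = bone_len, transitions = trans,
       lines_with_bone = lines_with_bone, mil = mil)
}

# Enumerate every s x s grid box explicitly.
oracle_box_count <- function(slice, s) {
  nr <- nrow(slice); nc <- ncol(slice)
  count <- 0L
  for (bi in seq_len(ceiling(nr / s))) {
    for (bj in seq_len(ceiling(nc / s))) {
      rows <- ((bi - 1) * s + 1):min(bi * s, nr)
      cols <- ((bj - 1) * s + 1):min(bj * s, nc)
      if (any(slice[rows, cols])) count <- count + 1L
    }
  }
  count
}

oracle_areas <- function(mask, voxel_size) {
  areas <- c()
  for (k in seq_len(dim(mask)[3])) {
    n <- 0L
    for (v in mask[, , k]) if (v) n <- n + 1L
    if (n > 0) areas <- c(areas, n * voxel_size[1] * voxel_size[2] / 100)
  }
  list(mean_area = mean(areas), min_area = min(areas))
}

# First load maximum followed by a drop > 10% before the load re-exceeds
# it; checks every local maximum by direct forward scan.
oracle_failure <- function(load) {
  n <- length(load)
  for (i in 2:(n - 1)) {
    is_max <- load[i] > load[i - 1]
    if (is_max) {
      # plateau: advance to its end, require a fall after it
      j <- i
      while (j < n && load[j + 1] == load[j]) j <- j + 1
      is_max <- j < n && load[j + 1] < load[j]
    }
    if (!is_max) next
    m <- load[i]
    lo <- Inf
    for (k in (i + 1):n) {
      if (load[k] > m) break
      if (load[k] < lo) lo <- load[k]
    }
    if (is.finite(lo) && lo < 0.9 * m) {
      return(list(detected = TRUE, failure_load = m, failure_index = i))
    }
  }
  list(detected = FALSE, failure_load = NA_real_, failure_index = NA_integer_)
}

# OLS via explicit design-matrix algebra (different route than the
# package's moment formulas).
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(x) - 2
  sigma2 <- sum(res^2) / df
  vc <- sigma2 * solve(t(X) %*% X)
  b <- unname(beta[2, 1])
  se <- unname(sqrt(vc[2, 2]))
  t <- b / se
  list(B = b, se_B = se, intercept = unname(beta[1, 1]),
       p = unname(2 * pt(-abs(t), df)), r = unname(cor(x, y)))
}

# Random piecewise-linear load curve with several segments; returns a
# valid curve list.
random_load_curve <- function(seed) {
  set.seed(seed)
  n_seg <- sample(3:7, 1)
  knots <- c(0, sort(runif(n_seg - 1)), 1) * 3
  levels <- runif(n_seg + 1, 0, 3000)
  n <- 60
  d <- seq(0, 3, length.out = n)
  load <- approx(knots, levels, xout = d)$y
  list(displacement = d, load = load)
}
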