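#' Bias-corrected percentile bootstrap confidence interval for a mean
#'
#' Nonparametric CI for the mean of a small sample (typically N = 4 biological
#' replicates). `n_boot` resamples of size `N` are drawn with replacement and
#' their means collected. The bias-correction factor is
#' `z0 = qnorm(p)` with `p` the proportion of bootstrap means *strictly below*
#' the observed mean (ties at the observed mean are not counted), clamped to
#' `[1/(2 n_boot), 1 - 1/(2 n_boot)]` so `z0` stays finite for degenerate
#' resample distributions. The bounds are the bootstrap-mean quantiles at
#' levels `pnorm(2 z0 -/+ z)`, where `z = qnorm((1 + conf)/2)`.
#'
#' For small N the bootstrap-mean distribution is highly discrete (at N = 4 it
#' has at most 35 distinct values), so the quantiles are extracted from a
#' smooth inverse CDF: the distinct resample means are placed at mid-mass
#' (Hazen) plotting positions of their empirical CDF and linearly
#' interpolated. This makes the Monte-Carlo bounds a smooth function of the
#' estimated CDF and convergent (at rate 1/sqrt(n_boot)) to the bounds
#' computed from exact enumeration of all `N^N` equiprobable resamples.
#'
#' @param values Numeric vector of N >= 2 observations.
#' @param conf Nominal confidence level in (0, 1); use [bonferroni_conf()] to
#'   adjust for simultaneous intervals across spots.
#' @param n_boot Number of bootstrap resamples (default 20000).
#' @param seed Optional integer seed; when supplied the caller's RNG state is
#'   left untouched.
#' @return Named numeric vector `c(cl = ..., cu = ...)`. If all values are
#'   identical the degenerate interval `(v, v)` is returned without
#'   resampling.
#' @examples
#' bc_bootstrap_ci(c(0.2, 0.3, 0.4, 0.5), conf = 0.95, seed = 1)
#' bc_bootstrap_ci(rep(0.3, 4))   # degenerate: (0.3, 0.3)
#' @export
bc_bootstrap_ci <- function(values, conf = 0.95, n_boot = 20000, seed = NULL) {
  stopifnot(is.numeric(values), conf > 0, conf < 1, n_boot >= 1)
  n <- length(values)
  if (n < 2L) stop("bootstrap CI requires at least 2 values")
  if (diff(range(values)) == 0) {
    return(c(cl = values[1L], cu = values[1L]))
  }
  boot_means <- with_seed(seed,
    colMeans(matrix(sample(values, n * n_boot, replace = TRUE), nrow = n)))
  bc_bounds(boot_means, mean(values), conf)
}

# Shared BC-percentile arithmetic: bias correction from the proportion of
# `means` strictly below `observed`, then smooth inverse-CDF quantiles.
# Exported mainly so that an exact-enumeration distribution of resample means
# can be pushed through the identical adjustment.
#' @param means Numeric vector of resample means (Monte-Carlo draws or the
#'   exhaustive enumeration, with multiplicity).
#' @param observed Observed sample mean.
#' @rdname bc_bootstrap_ci
#' @export
bc_bounds <- function(means, observed, conf) {
  m <- length(means)
  p <- sum(means < observed) / m
  p <- min(max(p, 1 / (2 * m)), 1 - 1 / (2 * m))
  z0 <- stats::qnorm(p)
  za <- stats::qnorm((1 + conf) / 2)
  levels <- stats::pnorm(c(2 * z0 - za, 2 * z0 + za))
  q <- midmass_quantile(means, levels)
  c(cl = q[1L], cu = q[2L])
}

# Inverse CDF of a (possibly heavily tied) sample, linearly interpolated
# between distinct values at mid-mass plotting positions; constant beyond the
# extreme values.
midmass_quantile <- function(x, probs) {
  tb <- table(x)
  xs <- as.numeric(names(tb))
  cnt <- as.numeric(tb)
  if (length(xs) == 1L) return(rep(xs, length(probs)))
  pk <- (cumsum(cnt) - 0.5 * cnt) / sum(cnt)
  stats::approx(pk, xs, xout = probs, rule = 2, ties = "ordered")$y
}

#' Bonferroni-adjusted confidence level
#'
#' Confidence level for simultaneous intervals: testing `m` spots at family
#' error rate `alpha` requires each interval at level `1 - alpha/m`.
#'
#' @param alpha Family-wise type I error rate (default 0.05).
#' @param m Number of simultaneous comparisons (>= 1); in the spot pipeline,
#'   the number of spots with phospho signal in at least one group.
#' @return The adjusted confidence level `1 - alpha/m`.
#' @examples
#' bonferroni_conf(0.05, 1)    # 0.95
#' bonferroni_conf(0.05, 59)   # ~0.99915
#' @export
bonferroni_conf <- function(alpha = 0.05, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  1 - alpha / m
}
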