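# Independent brute-force oracles used to validate the package's statistics.
# These deliberately re-derive each quantity from first principles rather
# than calling the implementation under test.

# Exact BC-percentile bounds from exhaustive enumeration of all N^N
# equiprobable resamples of `values` (256 resamples at N = 4). Self-contained:
# own bias correction, own interpolated inverse CDF.
enum_bc_ci <- function(values, conf) {
  n <- length(values)
  idx <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  means <- rowMeans(matrix(values[idx], nrow = nrow(idx)))
  M <- length(means)
  p <- sum(means < mean(values)) / M
  p <- min(max(p, 1 / (2 * M)), 1 - 1 / (2 * M))
  z0 <- qnorm(p)
  za <- qnorm((1 + conf) / 2)
  lv <- pnorm(c(2 * z0 - za, 2 * z0 + za))
  tb <- sort(unique(means))
  cnt <- vapply(tb, function(v) sum(means == v), numeric(1))
  pk <- (cumsum(cnt) - 0.5 * cnt) / M
  if (length(tb) == 1L) rep(tb, 2) else approx(pk, tb, xout = lv, rule = 2)$y
}

# Coverage indicator of the enumeration-based CI for a known true mean.
enum_bc_covers <- function(values, conf, true_mean) {
  ci <- enum_bc_ci(values, conf)
  ci[1] <= true_mean && true_mean <= ci[2]
}

# Two-sided Fisher exact P by explicit enumeration of all 2x2 tables with
# the observed margins, using binomial coefficients directly.
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  prob <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  obs <- choose(r1, a) * choose(r2, c) / choose(n, c1)
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney P for small tie-free samples by enumerating
# all assignments of pooled ranks to the x sample.
enum_mw_p <- function(x, y) {
  stopifnot(!anyDuplicated(c(x, y)))
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_obs <- sum(outer(x, y, ">"))
  combos <- combn(nx + ny, nx)
  us <- apply(combos, 2, function(ix) {
    xv <- pooled[ix]; yv <- pooled[-ix]
    sum(outer(xv, yv, ">"))
  })
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Brute-force UPGMA cophenetic matrix: at every step recompute every
# between-cluster distance as the plain mean over all cross pairs of the
# ORIGINAL distance matrix (no Lance-Williams recursion).
brute_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  labs <- rownames(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < best[1]) best <- c(dd, i, j)
    }
    i <- best[2]; j <- best[3]
    coph[clusters[[i]], clusters[[j]]] <- best[1]
    coph[clusters[[j]], clusters[[i]]] <- best[1]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# Ultrametric inequality check on a cophenetic matrix.
is_ultrametric <- function(m, tol = 1e-9) {
  n <- nrow(m)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (m[i, k] > max(m[i, j], m[j, k]) + tol) return(FALSE)
  }
  TRUE
}
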