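#' Group-level spot counts
#'
#' Counts, for each group, the reproducibly detected spots (total-protein
#' channel) and the phospho-positive spots (phospho channel detected in at
#' least `min_reps` replicates), plus the overlap structure of the two
#' phospho-positive sets: shared spots and group-unique spots (phospho signal
#' in one group only). Count identities
#' (`n_unique_g = n_phospho_g - n_shared`) are asserted on construction.
#'
#' @param treated,control Spot volume tables, already reproducibility-filtered.
#' @param min_reps Replicate threshold used for both channels (default 2).
#' @return A list of class `group_spot_counts` with elements
#'   `n_reproducible_treated/control`, `n_phospho_treated/control`,
#'   `n_shared_phospho`, `n_unique_treated/control`, and the underlying
#'   `phospho_spots_treated/control` id vectors.
#' @export
spot_group_counts <- function(treated, control, min_reps = 2) {
  count_group <- function(tab) {
    tot <- presence_counts(tab, "total")
    pho <- presence_counts(tab, "phospho")
    list(reproducible = names(tot)[tot >= min_reps],
         phospho = names(pho)[pho >= min_reps])
  }
  t <- count_group(treated)
  c_ <- count_group(control)
  shared <- intersect(t$phospho, c_$phospho)
  out <- list(
    n_reproducible_treated = length(t$reproducible),
    n_reproducible_control = length(c_$reproducible),
    n_phospho_treated = length(t$phospho),
    n_phospho_control = length(c_$phospho),
    n_shared_phospho = length(shared),
    n_unique_treated = length(setdiff(t$phospho, shared)),
    n_unique_control = length(setdiff(c_$phospho, shared)),
    phospho_spots_treated = t$phospho,
    phospho_spots_control = c_$phospho
  )
  stopifnot(out$n_unique_treated == out$n_phospho_treated - out$n_shared_phospho,
            out$n_unique_control == out$n_phospho_control - out$n_shared_phospho,
            out$n_unique_treated >= 0, out$n_unique_control >= 0)
  class(out) <- "group_spot_counts"
  out
}

#' @export
print.group_spot_counts <- function(x, ...) {
  cat(sprintf("reproducible spots: %d (treated) / %d (control)\n",
              x$n_reproducible_treated, x$n_reproducible_control))
  cat(sprintf("phospho-positive:   %d (treated) / %d (control), %d shared\n",
              x$n_phospho_treated, x$n_phospho_control, x$n_shared_phospho))
  cat(sprintf("group-unique:       %d (treated) / %d (control)\n",
              x$n_unique_treated, x$n_unique_control))
  invisible(x)
}

#' Phospho-positive spot percentage
#'
#' `100 * k / n` rounded to one decimal, the convention used when reporting
#' the share of phospho-stained spots among reproducible spots.
#'
#' @param k Number of phospho-positive spots.
#' @param n Number of reproducible spots (> 0, `k <= n`).
#' @return Percentage rounded to 1 decimal place.
#' @examples
#' phospho_percentage(46, 314)  # 14.6
#' @export
phospho_percentage <- function(k, n) {
  stopifnot(n > 0, k >= 0, k <= n)
  round(100 * k / n, 1)
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Exact two-sided P-value for independence in the 2x2 table
#' `rbind(c(a, b), c(c, d))`, using the standard sum-of-small-probabilities
#' convention: the probabilities of all tables with the same margins that are
#' no more probable than the observed one are summed (this is what
#' `stats::fisher.test()` computes; it is invariant under row and column
#' swaps). A degenerate table (a zero row or column margin) carries no
#' information and returns P = 1 with a warning.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise.
#' @return The two-tailed P-value in (0, 1].
#' @examples
#' fisher_exact_two_tailed(46, 268, 41, 267)
#' @export
fisher_exact_two_tailed <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (zero margin); P = 1")
    return(1)
  }
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The U statistic uses
#' midranks for ties. The P-value is exact (by enumeration of rank
#' assignments) when the pooled sample is small (`n_x + n_y <= exact_limit`)
#' and tie-free, and otherwise uses the normal approximation with tie
#' correction and continuity correction — the behaviour of
#' `stats::wilcox.test()`, which performs the computation.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_limit Pooled-size threshold for the exact P-value (default 12).
#' @return List with `U` (U statistic of `x`) and `p` (two-tailed P-value).
#' @examples
#' mann_whitney_two_tailed(c(1, 2), c(3, 4))  # exact P = 1/3
#' @export
mann_whitney_two_tailed <- function(x, y, exact_limit = 12) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= exact_limit && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}
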