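#' Phosphorylation rate of a spot
#'
#' `PR = P/T`: the ratio of the phospho-stain (Pro-Q Diamond) volume to the
#' total-protein (SYPRO Ruby) volume of the same spot on the same gel. PR is
#' not clamped — values above 1 are possible because the two stains have
#' unrelated response factors — but values above 1.5 trigger a warning as a
#' plausible sign of mismatched spots or saturated phospho signal.
#'
#' @param p_volume Phospho-channel volume(s), >= 0.
#' @param t_volume Total-channel volume(s), strictly > 0; a zero total volume
#'   leaves PR undefined and is an error (such replicates are excluded
#'   upstream).
#' @return `p_volume / t_volume`, vectorized.
#' @examples
#' phosphorylation_rate(0.5, 1.0)   # 0.5
#' phosphorylation_rate(0, 2.3)     # 0
#' @export
phosphorylation_rate <- function(p_volume, t_volume) {
  stopifnot(is.numeric(p_volume), is.numeric(t_volume),
            all(p_volume >= 0))
  if (any(t_volume <= 0)) {
    stop("undefined PR: total volume must be > 0")
  }
  pr <- p_volume / t_volume
  if (any(pr > 1.5)) {
    warning(sum(pr > 1.5), " PR value(s) above 1.5; check spot matching or saturation")
  }
  pr
}

#' Fold change of group-mean phosphorylation rates
#'
#' `FC = PR_treated / PR_control`, with ratios below one reported as their
#' negative reciprocal so that the magnitude always reads as a fold and the
#' sign as a direction: +2 means twice as phosphorylated in the treated
#' group, -2 twice as phosphorylated in the control. Consequently `|FC| >= 1`
#' always; `FC = +1` means no change. Spots with phospho signal in one group
#' only give `+Inf` (control zero) or `-Inf` (treated zero); both zero is an
#' error (the spot carries no phospho signal to compare).
#'
#' @param pr_treated,pr_control Group-mean PR values, >= 0 (vectorized).
#' @return Signed fold change(s); never in the open interval (-1, +1).
#' @examples
#' fold_change(0.08, 0.36)  # -4.5
#' fold_change(0.41, 0)     # +Inf
#' fold_change(0.2, 0.2)    # 1
#' @export
fold_change <- function(pr_treated, pr_control) {
  stopifnot(all(pr_treated >= 0), all(pr_control >= 0))
  if (any(pr_treated == 0 & pr_control == 0)) {
    stop("undefined FC: both group means are zero")
  }
  r <- pr_treated / pr_control  # Inf when control is 0
  out <- ifelse(pr_treated == 0, -Inf, ifelse(r >= 1, r, -1 / r))
  out
}

#' Relative change in phosphorylation rate
#'
#' `RC = DPR / |DPR_max|`, where `DPR` is the between-group difference in
#' mean PR for a spot and `DPR_max` the strongest difference over the set of
#' spots being summarised. Unlike the fold change, RC stays bounded in
#' `[-1, +1]` for group-unique spots (where FC is infinite), which makes it
#' usable as a clustering feature across the full significant set.
#'
#' The scaling constant is the maximum of `|DPR|`: the statistic's defining
#' bound `RC %in% [-1, +1]` forces the absolute maximum whenever the
#' strongest change is a decrease, and when the strongest change is an
#' increase (as in the reference dataset) this is identical to the signed
#' maximum. The spot attaining the (positive) maximum gets `RC = +1` exactly.
#'
#' @param dpr Numeric vector of per-spot PR differences (treated - control).
#' @return Numeric vector of RC values in `[-1, +1]`, `sign(RC) == sign(DPR)`.
#'   If every `dpr` is zero, a vector of zeros is returned with a warning.
#' @examples
#' relative_change(c(0.41, -0.28, 0.94))  # 0.436, -0.298, 1.000
#' @export
relative_change <- function(dpr) {
  stopifnot(is.numeric(dpr))
  scale <- max(abs(dpr))
  if (scale == 0) {
    warning("all PR differences are zero; RC set to 0")
    return(rep(0, length(dpr)))
  }
  dpr / scale
}

#' Significance call from two adjusted bootstrap intervals
#'
#' Decision rule for differential phosphorylation of one spot given its
#' per-group summaries (mean PR and Bonferroni-adjusted bootstrap CI):
#' \itemize{
#'   \item both group means zero: `"not_evaluable"` (no phospho signal at all);
#'   \item exactly one group zero: `"yes"` iff the nonzero group's adjusted
#'     lower bound excludes zero (`CL > 0`) — the qualitative
#'     (presence/absence) case;
#'   \item both nonzero: `"yes"` iff the two adjusted intervals do not
#'     overlap — the quantitative case.
#' }
#' Interval non-overlap at Bonferroni-adjusted levels is a conservative
#' simultaneous-inference rule; it is a documented package convention, since
#' interval-based group comparison admits several operators.
#'
#' @param summary_treated,summary_control Per-group summaries for the same
#'   spot: lists or one-row data frames with elements `mean_pr`, `ci_lower`,
#'   `ci_upper` (bounds may be `NA` when the mean is zero).
#' @return One of `"yes"`, `"no"`, `"not_evaluable"`.
#' @examples
#' significance_call(list(mean_pr = 0.08, ci_lower = 0.051, ci_upper = 0.108),
#'                   list(mean_pr = 0.36, ci_lower = 0.169, ci_upper = 0.696))
#' @export
significance_call <- function(summary_treated, summary_control) {
  mt <- summary_treated$mean_pr
  mc <- summary_control$mean_pr
  stopifnot(length(mt) == 1L, length(mc) == 1L)
  if (mt == 0 && mc == 0) return("not_evaluable")
  if (mt == 0 || mc == 0) {
    nz <- if (mt > 0) summary_treated else summary_control
    return(if (!is.na(nz$ci_lower) && nz$ci_lower > 0) "yes" else "no")
  }
  no_overlap <- summary_treated$ci_upper < summary_control$ci_lower ||
    summary_control$ci_upper < summary_treated$ci_lower
  if (no_overlap) "yes" else "no"
}
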