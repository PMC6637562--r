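# Per-spot replicate PR values for one group's table. A replicate contributes
# when the spot was detected on the total channel there; a missing phospho
# measurement on such a replicate means no phospho signal, i.e. PR = 0.
# Returns a named list of numeric vectors (one per spot).
pr_replicate_values <- function(table) {
  validate_spot_table(table)
  tot <- table[table$channel == "total", , drop = FALSE]
  if (nrow(tot) == 0L) return(structure(list(), names = character(0)))
  pho <- table[table$channel == "phospho", , drop = FALSE]
  key_t <- paste(tot$spot_id, tot$replicate, sep = "\r")
  key_p <- paste(pho$spot_id, pho$replicate, sep = "\r")
  p_vol <- pho$volume[match(key_t, key_p)]
  p_vol[is.na(p_vol)] <- 0
  usable <- tot$volume > 0
  if (!all(usable)) {
    warning(sum(!usable), " replicate measurement(s) with zero total volume excluded")
  }
  pr <- phosphorylation_rate(p_vol[usable], tot$volume[usable])
  split(pr, tot$spot_id[usable])
}

#' Differential phosphorylation analysis of two spot volume tables
#'
#' The central pipeline stage: given the (filtered, and where appropriate
#' normalized) spot volume tables of a treated and a control group, computes
#' per spot and group the replicate PR values, their mean and standard error,
#' and a bias-corrected percentile bootstrap CI at the Bonferroni-adjusted
#' level; then calls significance per spot and summarises effect sizes with
#' FC and RC.
#'
#' Conventions:
#' \itemize{
#'   \item The comparison universe is the union of spot ids in the two
#'     tables; the Bonferroni divisor `m` is the number of spots with phospho
#'     signal (mean PR > 0) in at least one group, one comparison per spot.
#'   \item A group in which a spot has no phospho signal gets mean PR 0 and a
#'     not-applicable CI (reported as `NA` bounds).
#'   \item RC is computed over the spots called significant (`rc_universe =
#'     "significant"`, the default, mirroring how the statistic is used for
#'     clustering) or over all evaluable spots (`"all"`).
#' }
#'
#' @param treated,control Spot volume tables (see [validate_spot_table()]),
#'   already passed through [reproducibility_filter()].
#' @param alpha Family-wise error rate for the simultaneous CIs (default 0.05).
#' @param n_boot Bootstrap resamples per CI (default 20000).
#' @param seed Integer seed making the whole analysis reproducible.
#' @param bonferroni_m Override for the Bonferroni divisor; `NULL` (default)
#'   derives it from the data as described above.
#' @param rc_universe `"significant"` or `"all"`.
#' @return An object of class `phospho_analysis`: a list with
#'   \describe{
#'     \item{summary}{data frame, one row per spot x group: `spot_id`,
#'       `group`, `n_reps`, `mean_pr`, `se_pr`, `ci_lower`, `ci_upper`,
#'       `applicable`.}
#'     \item{differential}{data frame, one row per spot: `spot_id`,
#'       `pr_treated`, `pr_control`, `dpr`, `fc`, `rc`, `significant`.}
#'     \item{m, conf_adjusted, alpha, n_boot, seed, groups}{run metadata.}
#'   }
#' @export
analyze_spot_set <- function(treated, control, alpha = 0.05, n_boot = 20000,
                             seed = 1, bonferroni_m = NULL,
                             rc_universe = c("significant", "all")) {
  rc_universe <- match.arg(rc_universe)
  prs_t <- pr_replicate_values(treated)
  prs_c <- pr_replicate_values(control)
  spots <- sort(union(names(prs_t), names(prs_c)))
  if (length(spots) == 0L) stop("no spots in either table")
  if (length(intersect(unique(treated$spot_id), unique(control$spot_id))) == 0L) {
    stop("spot universes of the two tables do not intersect; tables are not matched")
  }
  group_t <- unique(treated$group)[1L]
  group_c <- unique(control$group)[1L]
  if (identical(group_t, group_c)) {
    group_t <- paste0(group_t, ".treated")
    group_c <- paste0(group_c, ".control")
  }

  mean_of <- function(v) if (length(v) == 0L) 0 else mean(v)
  means_t <- vapply(spots, function(s) mean_of(prs_t[[s]]), numeric(1))
  means_c <- vapply(spots, function(s) mean_of(prs_c[[s]]), numeric(1))

  m <- if (is.null(bonferroni_m)) sum(means_t > 0 | means_c > 0) else bonferroni_m
  if (m < 1) stop("no spot has phospho signal in either group")
  conf <- bonferroni_conf(alpha, m)

  summarise_group <- function(s, values, group) {
    n <- length(values)
    mu <- mean_of(values)
    se <- if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_
    if (mu > 0 && n >= 2L) {
      ci <- bc_bootstrap_ci(values, conf = conf, n_boot = n_boot)
      data.frame(spot_id = s, group = group, n_reps = n, mean_pr = mu,
                 se_pr = se, ci_lower = ci[["cl"]], ci_upper = ci[["cu"]],
                 applicable = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(spot_id = s, group = group, n_reps = n, mean_pr = mu,
                 se_pr = if (mu == 0) NA_real_ else se,
                 ci_lower = NA_real_, ci_upper = NA_real_,
                 applicable = FALSE, stringsAsFactors = FALSE)
    }
  }

  summary_df <- with_seed(seed, {
    rows <- lapply(spots, function(s) {
      rbind(summarise_group(s, prs_t[[s]], group_t),
            summarise_group(s, prs_c[[s]], group_c))
    })
    do.call(rbind, rows)
  })
  rownames(summary_df) <- NULL

  sig <- vapply(spots, function(s) {
    significance_call(summary_df[summary_df$spot_id == s & summary_df$group == group_t, ],
                      summary_df[summary_df$spot_id == s & summary_df$group == group_c, ])
  }, character(1))

  dpr <- means_t - means_c
  fc <- rep(NA_real_, length(spots))
  evaluable <- means_t > 0 | means_c > 0
  fc[evaluable] <- fold_change(means_t[evaluable], means_c[evaluable])

  rc <- rep(NA_real_, length(spots))
  in_rc <- if (rc_universe == "significant") sig == "yes" else evaluable
  if (any(in_rc) && any(dpr[in_rc] != 0)) {
    rc[in_rc] <- relative_change(dpr[in_rc])
  } else if (any(in_rc)) {
    rc[in_rc] <- suppressWarnings(relative_change(dpr[in_rc]))
  }

  differential <- data.frame(
    spot_id = spots, pr_treated = means_t, pr_control = means_c,
    dpr = dpr, fc = fc, rc = rc, significant = sig,
    stringsAsFactors = FALSE, row.names = NULL
  )

  structure(list(summary = summary_df, differential = differential,
                 m = m, conf_adjusted = conf, alpha = alpha, n_boot = n_boot,
                 seed = seed, groups = c(treated = group_t, control = group_c)),
            class = "phospho_analysis")
}

#' @export
print.phospho_analysis <- function(x, ...) {
  n_sig <- sum(x$differential$significant == "yes")
  cat("Differential phosphorylation analysis\n")
  cat(sprintf("  groups: %s vs %s\n", x$groups[["treated"]], x$groups[["control"]]))
  cat(sprintf("  spots analyzed (phospho in >=1 group): %d of %d in universe\n",
              x$m, nrow(x$differential)))
  cat(sprintf("  significant spots: %d (alpha = %g, adjusted conf = %.6f, n_boot = %d)\n",
              n_sig, x$alpha, x$conf_adjusted, x$n_boot))
  invisible(x)
}

#' Effect statistics from a published-style summary table
#'
#' Recomputes the differential record (DPR, FC, RC, significance) directly
#' from a per-spot summary of group means and adjusted CIs — the form in
#' which 2-DE phosphoproteome results are published — rather than from raw
#' replicate volumes. This is the entry point for auditing reported FC/RC
#' values against reported group means.
#'
#' @param summary_wide Data frame with one row per spot and columns
#'   `spot_id`, `pr_mean_treated`, `ci_lower_treated`, `ci_upper_treated`,
#'   `pr_mean_control`, `ci_lower_control`, `ci_upper_control` (CI columns
#'   `NA` where the group mean is zero). Extra columns (e.g. `protein`) are
#'   carried through.
#' @param rc_universe As in [analyze_spot_set()].
#' @return Data frame with `spot_id`, carried-through annotation columns,
#'   `dpr`, `fc`, `rc`, `significant`.
#' @export
differential_from_summary <- function(summary_wide,
                                      rc_universe = c("significant", "all")) {
  rc_universe <- match.arg(rc_universe)
  required <- c("spot_id", "pr_mean_treated", "pr_mean_control")
  missing_cols <- setdiff(required, names(summary_wide))
  if (length(missing_cols) > 0L) {
    stop("summary is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- summary_wide
  for (cc in c("ci_lower_treated", "ci_upper_treated",
               "ci_lower_control", "ci_upper_control")) {
    if (is.null(x[[cc]])) x[[cc]] <- NA_real_
  }
  sig <- vapply(seq_len(nrow(x)), function(i) {
    significance_call(
      list(mean_pr = x$pr_mean_treated[i],
           ci_lower = x$ci_lower_treated[i], ci_upper = x$ci_upper_treated[i]),
      list(mean_pr = x$pr_mean_control[i],
           ci_lower = x$ci_lower_control[i], ci_upper = x$ci_upper_control[i]))
  }, character(1))
  dpr <- x$pr_mean_treated - x$pr_mean_control
  evaluable <- x$pr_mean_treated > 0 | x$pr_mean_control > 0
  fc <- rep(NA_real_, nrow(x))
  fc[evaluable] <- fold_change(x$pr_mean_treated[evaluable], x$pr_mean_control[evaluable])
  rc <- rep(NA_real_, nrow(x))
  in_rc <- if (rc_universe == "significant") sig == "yes" else evaluable
  if (any(in_rc)) rc[in_rc] <- relative_change(dpr[in_rc])
  ann <- setdiff(names(x), c("pr_mean_treated", "se_treated", "ci_lower_treated",
                             "ci_upper_treated", "pr_mean_control", "se_control",
                             "ci_lower_control", "ci_upper_control"))
  out <- cbind(x[, ann, drop = FALSE],
               data.frame(pr_treated = x$pr_mean_treated,
                          pr_control = x$pr_mean_control,
                          dpr = dpr, fc = fc, rc = rc, significant = sig,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
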