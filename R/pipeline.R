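#' End-to-end pipeline runners
#'
#' File-based orchestration of the analysis stages, mirroring how the results
#' of a dual-stain 2-DE study are reported: a per-spot summary table of group
#' means with adjusted CIs, an effect-size table (FC with `+inf`/`-inf`
#' sentinels, RC), a machine-readable summary of the group-level statistics,
#' and the UPGMA clustering outputs. Every output embeds the run seed and a
#' hash of the effective configuration, so two runs with identical inputs are
#' byte-identical.
#'
#' @name pipeline
NULL

meta_lines <- function(cfg_hash, seed) {
  c(sprintf("config_hash: %s", cfg_hash), sprintf("seed: %d", as.integer(seed)))
}

#' @param config A [sim_config()] (or preset name for convenience).
#' @param out_dir Output directory, created if needed.
#' @return `run_simulation()`: invisible named vector of the paths written
#'   (`treated`, `control`, `truth`, `config`).
#' @rdname pipeline
#' @export
run_simulation <- function(config, out_dir) {
  if (is.character(config)) config <- scenario_preset(config)
  if (!inherits(config, "sim_config")) stop("config must be a sim_config or preset name")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_spot_table(config)
  h <- config_hash(unclass(config))
  paths <- c(treated = file.path(out_dir, "treated.csv"),
             control = file.path(out_dir, "control.csv"),
             truth = file.path(out_dir, "truth.csv"),
             config = file.path(out_dir, "config.yaml"))
  write_spot_table(sim$treated, paths[["treated"]], meta = meta_lines(h, config$seed))
  write_spot_table(sim$control, paths[["control"]], meta = meta_lines(h, config$seed))
  con <- file(paths[["truth"]], "wt")
  writeLines(paste0("# ", meta_lines(h, config$seed)), con)
  utils::write.csv(sim$truth, con, row.names = FALSE, quote = FALSE)
  close(con)
  cfg <- unclass(config)
  cfg$phospho_fractions <- apply(cfg$phospho_fractions, 2, identity, simplify = FALSE)
  cfg$detection_prob <- apply(cfg$detection_prob, 2, identity, simplify = FALSE)
  yaml::write_yaml(c(list(config_hash = h), cfg), paths[["config"]])
  invisible(paths)
}

#' @param treated,control Spot volume tables or paths to their CSVs.
#' @param alpha,n_boot,min_reps,seed,bonferroni_m,rc_universe Analysis
#'   parameters, see [analyze_spot_set()] and [reproducibility_filter()].
#' @param normalize Whether to apply [normalize_total_valid_spot()] first
#'   (default `FALSE`: simulated volumes and pre-normalized exports are
#'   already on a common scale).
#' @return `run_analysis()`: invisibly, the `phospho_analysis` object; side
#'   effect: writes `pr_summary.csv`, `pr_changes.csv`, `analysis_summary.json`
#'   in `out_dir`.
#' @rdname pipeline
#' @export
run_analysis <- function(treated, control, out_dir, alpha = 0.05,
                         n_boot = 20000, min_reps = 2, seed = 1,
                         bonferroni_m = NULL,
                         rc_universe = c("significant", "all"),
                         normalize = FALSE) {
  rc_universe <- match.arg(rc_universe)
  if (is.character(treated)) treated <- read_spot_table(treated)
  if (is.character(control)) control <- read_spot_table(control)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (normalize) {
    treated <- normalize_total_valid_spot(treated)
    control <- normalize_total_valid_spot(control)
  }
  treated <- reproducibility_filter(treated, min_reps = min_reps)
  control <- reproducibility_filter(control, min_reps = min_reps)
  res <- analyze_spot_set(treated, control, alpha = alpha, n_boot = n_boot,
                          seed = seed, bonferroni_m = bonferroni_m,
                          rc_universe = rc_universe)
  cfg <- list(alpha = alpha, n_boot = n_boot, min_reps = min_reps, seed = seed,
              bonferroni_m = res$m, rc_universe = rc_universe,
              normalize = normalize)
  h <- config_hash(cfg)

  # wide per-spot summary, reported at 2 decimals like a published table,
  # full precision retained in the JSON/differential outputs
  s <- res$summary
  gt <- res$groups[["treated"]]; gc_ <- res$groups[["control"]]
  wide <- merge(
    stats::setNames(s[s$group == gt, c("spot_id", "mean_pr", "se_pr", "ci_lower", "ci_upper")],
                    c("spot_id", "pr_mean_treated", "se_treated", "ci_lower_treated", "ci_upper_treated")),
    stats::setNames(s[s$group == gc_, c("spot_id", "mean_pr", "se_pr", "ci_lower", "ci_upper")],
                    c("spot_id", "pr_mean_control", "se_control", "ci_lower_control", "ci_upper_control")),
    by = "spot_id", all = TRUE)
  wide <- wide[order(wide$spot_id), ]
  num <- vapply(wide, is.numeric, logical(1))
  wide[num] <- lapply(wide[num], function(x) round(x, 3))

  con <- file(file.path(out_dir, "pr_summary.csv"), "wt")
  writeLines(paste0("# ", meta_lines(h, seed)), con)
  utils::write.csv(wide, con, row.names = FALSE, quote = TRUE, na = "NA")
  close(con)

  diff_out <- res$differential
  diff_out$fc <- format_fc(diff_out$fc)
  diff_out$rc <- round(diff_out$rc, 2)
  num <- vapply(diff_out, is.numeric, logical(1))
  diff_out[num] <- lapply(diff_out[num], function(x) round(x, 4))
  con <- file(file.path(out_dir, "pr_changes.csv"), "wt")
  writeLines(paste0("# ", meta_lines(h, seed)), con)
  utils::write.csv(diff_out, con, row.names = FALSE, quote = TRUE, na = "NA")
  close(con)

  counts <- spot_group_counts(treated, control, min_reps = min_reps)
  sig <- res$differential[res$differential$significant == "yes", ]
  mw <- if (nrow(sig) >= 2) {
    mann_whitney_two_tailed(sig$pr_treated, sig$pr_control)
  } else list(U = NA, p = NA)
  fisher_p <- fisher_exact_two_tailed(
    counts$n_phospho_treated, counts$n_reproducible_treated - counts$n_phospho_treated,
    counts$n_phospho_control, counts$n_reproducible_control - counts$n_phospho_control)
  n_unique_sig <- sum(sig$pr_treated == 0 | sig$pr_control == 0)
  summary_json <- list(
    config = c(cfg, list(config_hash = h)),
    groups = as.list(res$groups),
    counts = counts[c("n_reproducible_treated", "n_reproducible_control",
                      "n_phospho_treated", "n_phospho_control",
                      "n_shared_phospho", "n_unique_treated", "n_unique_control")],
    phospho_percent_treated = phospho_percentage(counts$n_phospho_treated,
                                                 counts$n_reproducible_treated),
    phospho_percent_control = phospho_percentage(counts$n_phospho_control,
                                                 counts$n_reproducible_control),
    fisher_p_phospho_share = fisher_p,
    n_analyzed = res$m,
    n_significant = nrow(sig),
    n_significant_unique = n_unique_sig,
    mean_pr_treated_significant = if (nrow(sig)) mean(sig$pr_treated) else NA,
    mean_pr_control_significant = if (nrow(sig)) mean(sig$pr_control) else NA,
    mean_pr_ratio = if (nrow(sig) && mean(sig$pr_control) > 0) {
      mean(sig$pr_treated) / mean(sig$pr_control)
    } else NA,
    mann_whitney_U = mw$U, mann_whitney_p = mw$p,
    conf_adjusted = res$conf_adjusted
  )
  jsonlite::write_json(summary_json, file.path(out_dir, "analysis_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(res)
}

#' @param changes A differential table (e.g. `differential` element of a
#'   `phospho_analysis`, [dfd_reference_changes()], or a `pr_changes.csv`
#'   path); needs `rc` plus `spot_id`/`protein` labels.
#' @param conf Confidence level for the cluster-mean CIs (default 0.99).
#' @param metric Distance metric, see [rc_distance_matrix()].
#' @return `run_clustering()`: invisibly, a list with the tree, the cluster
#'   membership data frame and the cluster summary; writes `dendrogram.nwk`,
#'   `clusters.csv`, `cluster_summary.json`.
#' @rdname pipeline
#' @export
run_clustering <- function(changes, out_dir, conf = 0.99, n_boot = 20000,
                           seed = 1, metric = c("magnitude", "signed")) {
  metric <- match.arg(metric)
  if (is.character(changes)) {
    changes <- utils::read.csv(changes, comment.char = "#",
                               stringsAsFactors = FALSE,
                               colClasses = c(spot_id = "character"))
    if (is.character(changes$fc)) changes$fc <- parse_fc(changes$fc)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  keep <- !is.na(changes$rc)
  if ("significant" %in% names(changes)) keep <- keep & changes$significant == "yes"
  x <- changes[keep, , drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 spots with RC values to cluster")
  labels <- if ("protein" %in% names(x) && !anyDuplicated(x$protein)) {
    x$protein
  } else x$spot_id
  rc <- stats::setNames(x$rc, labels)

  cfg <- list(conf = conf, n_boot = n_boot, seed = seed, metric = metric)
  h <- config_hash(cfg)
  tree <- upgma(rc_distance_matrix(rc, metric = metric))
  clusters <- cut_two_clusters(tree)
  summary_df <- cluster_mean_ci(clusters, rc, conf = conf, n_boot = n_boot,
                                seed = seed)
  write_newick(tree, file.path(out_dir, "dendrogram.nwk"))

  member_rows <- do.call(rbind, lapply(seq_len(nrow(summary_df)), function(i) {
    data.frame(label = summary_df$members[[i]],
               cluster_id = summary_df$cluster_id[i], stringsAsFactors = FALSE)
  }))
  # upgma() sanitises labels for Newick only; clusters.csv keeps originals
  member_rows$rc <- rc[member_rows$label]
  member_rows$abs_rc <- abs(member_rows$rc)
  con <- file(file.path(out_dir, "clusters.csv"), "wt")
  writeLines(paste0("# ", meta_lines(h, seed)), con)
  utils::write.csv(member_rows, con, row.names = FALSE, quote = TRUE)
  close(con)

  jsonlite::write_json(list(
    config = c(cfg, list(config_hash = h)),
    clusters = lapply(seq_len(nrow(summary_df)), function(i) {
      list(cluster_id = summary_df$cluster_id[i], n = summary_df$n[i],
           mean_abs_rc = summary_df$mean_abs_rc[i],
           ci_lower = summary_df$ci_lower[i], ci_upper = summary_df$ci_upper[i],
           members = summary_df$members[[i]])
    }),
    clusters_distinct = attr(summary_df, "distinct")
  ), file.path(out_dir, "cluster_summary.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(list(tree = tree, members = member_rows, summary = summary_df))
}

#' @return `run_report()`: the report text, invisibly; also printed to the
#'   console and written to `report.txt` in `out_dir`.
#' @rdname pipeline
#' @export
run_report <- function(out_dir) {
  path <- file.path(out_dir, "analysis_summary.json")
  if (!file.exists(path)) {
    stop("no analysis_summary.json in ", out_dir, "; run run_analysis() first")
  }
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "g")
  lines <- c(
    "Differential phosphoproteome analysis report",
    "============================================",
    sprintf("groups: %s (treated) vs %s (control)", s$groups$treated, s$groups$control),
    sprintf("reproducible spots: %d / %d", s$counts$n_reproducible_treated,
            s$counts$n_reproducible_control),
    sprintf("phospho-positive: %d (%.1f%%) / %d (%.1f%%), shared %d, unique %d / %d",
            s$counts$n_phospho_treated, s$phospho_percent_treated,
            s$counts$n_phospho_control, s$phospho_percent_control,
            s$counts$n_shared_phospho, s$counts$n_unique_treated,
            s$counts$n_unique_control),
    sprintf("Fisher exact two-tailed P (phospho share): %s", fmt(s$fisher_p_phospho_share)),
    sprintf("spots analyzed: %d; significant: %d (of which group-unique: %d)",
            s$n_analyzed, s$n_significant, s$n_significant_unique),
    sprintf("mean PR over significant spots: %s (treated) vs %s (control), ratio %s",
            fmt(s$mean_pr_treated_significant), fmt(s$mean_pr_control_significant),
            fmt(s$mean_pr_ratio)),
    sprintf("Mann-Whitney two-tailed P (significant-spot PR columns): %s",
            fmt(s$mann_whitney_p)),
    sprintf("adjusted per-spot confidence level: %s", fmt(s$conf_adjusted, 6)),
    sprintf("[n_boot %d, seed %d, config %s]", s$config$n_boot, s$config$seed,
            s$config$config_hash)
  )
  cluster_path <- file.path(out_dir, "cluster_summary.json")
  if (file.exists(cluster_path)) {
    cl <- jsonlite::read_json(cluster_path, simplifyVector = FALSE)
    lines <- c(lines, "", "UPGMA clusters (|RC| means):")
    for (ci in cl$clusters) {
      lines <- c(lines, sprintf("  cluster %d (n=%d): mean |RC| %s, CI (%s, %s)",
                                ci$cluster_id, ci$n, fmt(ci$mean_abs_rc),
                                fmt(ci$ci_lower), fmt(ci$ci_upper)))
    }
    lines <- c(lines, sprintf("  clusters distinct: %s", cl$clusters_distinct))
  }
  writeLines(lines, file.path(out_dir, "report.txt"))
  cat(lines, sep = "\n")
  invisible(lines)
}
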