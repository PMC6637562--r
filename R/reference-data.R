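#' Bundled DFD meat phosphoproteome reference dataset
#'
#' Summary-level results of a published 2-DE phosphoproteome comparison of
#' bovine dark-firm-dry (DFD, the treated group) versus normal (control)
#' longissimus thoracis meat: the 32 protein spots with significant
#' differential phosphorylation, with per-group mean PR, standard error and
#' Bonferroni-adjusted 95% bias-corrected percentile bootstrap CI bounds over
#' N = 4 biological replicates (`dfd_reference_summary()`), and the published
#' fold-change / relative-change values for the same spots
#' (`dfd_reference_changes()`). Raw replicate volumes were not published;
#' these summary tables are the fixed reference against which the package's
#' effect-statistic code is audited (see [differential_from_summary()]).
#'
#' @return `dfd_reference_summary()`: data frame with `spot_id`, `protein`,
#'   and per-group `pr_mean_*`, `se_*`, `ci_lower_*`, `ci_upper_*` columns
#'   (`*_treated` = DFD). `dfd_reference_changes()`: data frame with
#'   `spot_id`, `protein`, `fc` (`+inf`/`-inf` sentinels parsed to
#'   `+Inf`/`-Inf`) and `rc`.
#' @examples
#' ref <- dfd_reference_summary()
#' mean(ref$pr_mean_treated)   # ~0.33
#' @export
dfd_reference_summary <- function() {
  path <- system.file("extdata", "dfd_spot_summary.csv", package = "phosphoRate",
                      mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = c(spot_id = "character"))
}

#' @rdname dfd_reference_summary
#' @export
dfd_reference_changes <- function() {
  path <- system.file("extdata", "dfd_spot_changes.csv", package = "phosphoRate",
                      mustWork = TRUE)
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                       colClasses = c(spot_id = "character", fc = "character"))
  x$fc <- parse_fc(x$fc)
  x
}

# "+inf"/"-inf" CSV sentinels <-> numeric fold changes
parse_fc <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[trimws(x) %in% c("+inf", "inf", "Inf", "+Inf")] <- Inf
  out[trimws(x) %in% c("-inf", "-Inf")] <- -Inf
  out
}

format_fc <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(is.infinite(x), ifelse(x > 0, "+inf", "-inf"),
                formatC(x, digits = 10, format = "g")))
}
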