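#' Total valid spot normalization
#'
#' Rescales every gel image so that the volumes of its detected (valid) spots
#' sum to a common reference. Each `(group, replicate, channel)` combination
#' is one scanned image; within an image every volume is divided by the image
#' total and multiplied by `reference` (default `1e6`, the ppm convention).
#' This removes image-level multiplicative differences in staining intensity,
#' exposure and loading. The choice of reference constant is immaterial for
#' the phosphorylation rate, which is a ratio of two volumes of the same spot.
#'
#' Normalization is idempotent and invariant to per-image rescaling of the
#' input: multiplying all volumes of one image by any constant leaves the
#' normalized table unchanged.
#'
#' @param table A spot volume `data.frame` (see [validate_spot_table()]).
#' @param reference Post-normalization total volume per image (default `1e6`).
#' @return The table with normalized volumes, same row order.
#' @export
normalize_total_valid_spot <- function(table, reference = 1e6) {
  validate_spot_table(table)
  if (nrow(table) == 0L) stop("cannot normalize an empty spot table")
  gel <- paste(table$group, table$replicate, table$channel, sep = "\r")
  totals <- tapply(table$volume, gel, sum)
  zero <- names(totals)[totals == 0]
  if (length(zero) > 0L) {
    stop("degenerate gel image (all volumes zero): ",
         gsub("\r", "/", zero[1L]))
  }
  table$volume <- table$volume / as.numeric(totals[gel]) * reference
  table
}

#' Replicate-reproducibility filter
#'
#' Keeps, within each group, only spots detected on at least `min_reps`
#' replicate gels. Detection is assessed on the total-protein channel: a spot
#' must exist reproducibly as a protein before its phosphorylation status is
#' considered, while phospho-channel presence is retained as recorded and
#' evaluated separately (e.g. by [spot_group_counts()]). Filtering is
#' per-group, so a spot may survive in one group only — such group-unique
#' spots are the qualitative signal the downstream statistics are designed to
#' handle.
#'
#' @param table A spot volume `data.frame`.
#' @param min_reps Minimum number of replicates with the spot detected
#'   (default 2, the "at least two of four" rule).
#' @param channel Channel on which detection is assessed (default `"total"`).
#' @return The filtered table (possibly empty). Raising `min_reps` can only
#'   remove spots, never add them.
#' @export
reproducibility_filter <- function(table, min_reps = 2, channel = "total") {
  validate_spot_table(table)
  stopifnot(min_reps >= 1)
  if (nrow(table) == 0L) return(table)
  keep_rows <- rep(FALSE, nrow(table))
  for (g in unique(table$group)) {
    in_g <- table$group == g
    counts <- presence_counts(table[in_g, , drop = FALSE], channel)
    kept_spots <- names(counts)[counts >= min_reps]
    keep_rows[in_g & table$spot_id %in% kept_spots] <- TRUE
  }
  table[keep_rows, , drop = FALSE]
}
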