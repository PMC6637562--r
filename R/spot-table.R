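#' Spot volume tables
#'
#' A spot volume table is a long-format `data.frame` with one row per
#' measured spot volume: columns `spot_id` (character), `group` (character),
#' `replicate` (integer, 1..N biological replicates), `channel` (`"phospho"`
#' for the Pro-Q Diamond image, `"total"` for the SYPRO Ruby image) and
#' `volume` (non-negative densitometric volume in arbitrary units). A spot
#' that was not detected on a given replicate gel simply has no row for that
#' (spot, replicate, channel) combination; absence is never encoded as a zero
#' volume.
#'
#' @param x A `data.frame` to validate as a spot volume table.
#' @return `validate_spot_table()` returns `x` invisibly after checking the
#'   column contract, uniqueness of `(spot_id, group, replicate, channel)`
#'   and non-negativity of volumes; it stops with an informative error (and
#'   the offending row number where applicable) otherwise.
#' @seealso [read_spot_table()], [normalize_total_valid_spot()],
#'   [reproducibility_filter()]
#' @export
validate_spot_table <- function(x) {
  required <- c("spot_id", "group", "replicate", "channel", "volume")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("spot table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(x) > 0L) {
    bad_channel <- which(!x$channel %in% c("phospho", "total"))
    if (length(bad_channel) > 0L) {
      stop("invalid channel '", x$channel[bad_channel[1L]], "' at row ",
           bad_channel[1L], " (must be 'phospho' or 'total')")
    }
    neg <- which(!is.finite(x$volume) | x$volume < 0)
    if (length(neg) > 0L) {
      stop("negative or non-finite volume at row ", neg[1L])
    }
    key <- paste(x$spot_id, x$group, x$replicate, x$channel, sep = "\r")
    dup <- which(duplicated(key))
    if (length(dup) > 0L) {
      stop("duplicate (spot_id, group, replicate, channel) key at row ", dup[1L])
    }
  }
  invisible(x)
}

#' Read and write spot volume tables
#'
#' CSV I/O for the long spot-volume format (`spot_id,group,replicate,channel,
#' volume`, UTF-8, `#` comment lines ignored). Volumes are written with 17
#' significant digits so that a write/read cycle reproduces them bit-exactly.
#'
#' @param path Path to a CSV file.
#' @return `read_spot_table()` returns a validated spot volume `data.frame`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' tab <- data.frame(spot_id = "S001", group = "DFD", replicate = 1:2,
#'                   channel = "total", volume = c(1200.5, 980))
#' write_spot_table(tab, tf)
#' identical(read_spot_table(tf)$volume, tab$volume)
#' @export
read_spot_table <- function(path) {
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                       colClasses = c(spot_id = "character", group = "character"))
  validate_spot_table(x)
  x$replicate <- as.integer(x$replicate)
  x$volume <- as.numeric(x$volume)
  x
}

#' @param table A spot volume `data.frame`.
#' @param meta Optional character vector of metadata lines to embed as
#'   leading `#` comments (e.g. a config hash and seed).
#' @rdname read_spot_table
#' @export
write_spot_table <- function(table, path, meta = NULL) {
  validate_spot_table(table)
  out <- table[, c("spot_id", "group", "replicate", "channel", "volume")]
  out$volume <- formatC(out$volume, digits = 17, format = "g")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", meta), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Spot metadata and protein-fragment flagging
#'
#' Spot metadata carries the gel-observed molecular mass (kDa) and isoelectric
#' point of each spot together with, when the spot has been identified, the
#' theoretical molecular mass of the full-length protein. Spots whose observed
#' mass falls well below the theoretical full-length mass are degradation
#' fragments and are excluded from differential analysis.
#'
#' The threshold below which a spot counts as a fragment is a tunable default
#' (`observed < ratio_threshold * theoretical`, default 0.8): the comparison
#' of observed and theoretical mass is standard practice but no universal
#' cutoff exists.
#'
#' @param observed_mr Observed molecular mass on the gel, kDa (> 0).
#' @param theoretical_mr Theoretical full-length mass, kDa; `NA` when the
#'   spot is unidentified.
#' @param ratio_threshold Fraction of the theoretical mass below which the
#'   spot is flagged (default 0.8).
#' @return Logical vector: `TRUE` = fragment (exclude), `FALSE` = intact,
#'   `NA` = not evaluable (no theoretical mass; spot is retained).
#' @examples
#' flag_fragment(20, 60)        # clear fragment
#' flag_fragment(42.2, 42.4)    # intact isoform
#' flag_fragment(30, NA)        # not evaluable -> NA
#' @export
flag_fragment <- function(observed_mr, theoretical_mr, ratio_threshold = 0.8) {
  stopifnot(is.numeric(observed_mr), all(is.na(observed_mr) | observed_mr > 0),
            ratio_threshold > 0)
  ifelse(is.na(theoretical_mr), NA, observed_mr < ratio_threshold * theoretical_mr)
}

#' @param path Path to a spot metadata CSV with columns
#'   `spot_id,observed_mr,observed_pi,theoretical_mr,protein_label`.
#' @rdname flag_fragment
#' @export
read_spot_meta <- function(path) {
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                       colClasses = c(spot_id = "character"))
  required <- c("spot_id", "observed_mr", "observed_pi")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("spot metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(x$observed_mr <= 0, na.rm = TRUE)) stop("observed_mr must be > 0")
  if (any(x$observed_pi <= 0 | x$observed_pi >= 14, na.rm = TRUE)) {
    stop("observed_pi must lie in (0, 14)")
  }
  x
}

# Count, per spot, the replicates on which a channel was measured in `tab`
# (one group's rows). Returns a named integer vector over spot ids.
presence_counts <- function(tab, channel) {
  sub <- tab[tab$channel == channel, , drop = FALSE]
  if (nrow(sub) == 0L) return(integer(0))
  counts <- tapply(sub$replicate, sub$spot_id, function(r) length(unique(r)))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}
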