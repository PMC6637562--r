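#' RC distance matrix between phosphoproteins
#'
#' Pairwise dissimilarity of spots (or proteins) from their relative-change
#' values. The default metric is `d(i, j) = ||rc_i| - |rc_j||`, the absolute
#' difference of RC magnitudes: spots are grouped by the *strength* of their
#' phosphorylation change regardless of direction, so a strong decrease and a
#' strong increase cluster together. The signed alternative
#' `d(i, j) = |rc_i - rc_j|` is available via `metric = "signed"`. Both are
#' one-dimensional embeddings, hence valid metrics (triangle inequality
#' holds).
#'
#' @param rc_values Named numeric vector of RC values; names are the leaf
#'   labels.
#' @param metric `"magnitude"` (default, distance between |RC| values) or
#'   `"signed"` (distance between signed RC values).
#' @return Symmetric matrix with zero diagonal and the labels as dimnames.
#' @export
rc_distance_matrix <- function(rc_values, metric = c("magnitude", "signed")) {
  metric <- match.arg(metric)
  if (length(rc_values) < 2L) stop("need at least 2 labelled RC values")
  if (is.null(names(rc_values))) stop("rc_values must be named")
  v <- if (metric == "magnitude") abs(rc_values) else rc_values
  d <- abs(outer(v, v, "-"))
  dimnames(d) <- list(names(rc_values), names(rc_values))
  d
}

#' UPGMA clustering
#'
#' Unweighted pair-group method with arithmetic averaging: repeatedly merge
#' the two closest clusters, with the distance between clusters defined as
#' the arithmetic mean of all cross-pair distances of their members, until
#' one tree remains. The height of a merge node is half the merge distance
#' (so the cophenetic distance between two leaves — twice the height of their
#' lowest common ancestor — equals the average-linkage distance at which they
#' join). Leaves sit at height 0 and every parent is at least as high as its
#' children, i.e. the output is ultrametric.
#'
#' Labels are sorted before clustering and distance ties are broken in favour
#' of the pair that comes first in sorted-label order, so the result is
#' deterministic and invariant to input permutation.
#'
#' @param dist Symmetric, non-negative distance matrix with zero diagonal
#'   (class `matrix` or `dist`), labelled via dimnames.
#' @param labels Optional label vector overriding the dimnames.
#' @return The root node, class `dendro_node`: a list with `height`,
#'   `children` (list of two `dendro_node`s, `NULL` for leaves), `label`
#'   (leaves only) and `members` (sorted leaf labels under the node).
#' @seealso [cut_two_clusters()], [tree_cophenetic()], [as_newick()]
#' @export
upgma <- function(dist, labels = NULL) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 leaves")
  if (is.null(labels)) labels <- rownames(d)
  if (is.null(labels)) labels <- sprintf("L%0*d", nchar(n), seq_len(n))
  stopifnot(length(labels) == n, !anyDuplicated(labels))
  if (any(d < 0) || any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0)) {
    stop("distance matrix must be symmetric, non-negative, with zero diagonal")
  }
  ord <- order(labels)
  d <- d[ord, ord, drop = FALSE]
  labels <- labels[ord]

  nodes <- lapply(labels, function(l) {
    structure(list(height = 0, children = NULL, label = l, members = l),
              class = "dendro_node")
  })
  sizes <- rep(1L, n)
  active <- seq_len(n)
  D <- d

  while (length(active) > 1L) {
    k <- length(active)
    # locate minimum over i < j; which.min on the masked matrix scans
    # column-major, which is exactly lowest-label-order tie-breaking given
    # the list is kept sorted by smallest member label
    sub <- D[active, active, drop = FALSE]
    sub[!upper.tri(sub)] <- Inf
    ij <- arrayInd(which.min(t(sub)), c(k, k))  # row-major scan: (i, j), i<j
    i <- ij[1, 2]; j <- ij[1, 1]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    ai <- active[i]; aj <- active[j]
    h <- D[ai, aj] / 2
    merged <- structure(
      list(height = h,
           children = list(nodes[[ai]], nodes[[aj]]),
           label = NULL,
           members = sort(c(nodes[[ai]]$members, nodes[[aj]]$members))),
      class = "dendro_node")
    # Lance-Williams update for UPGMA: size-weighted mean of cross distances
    others <- setdiff(active, c(ai, aj))
    if (length(others) > 0L) {
      D[ai, others] <- (sizes[ai] * D[ai, others] + sizes[aj] * D[aj, others]) /
        (sizes[ai] + sizes[aj])
      D[others, ai] <- D[ai, others]
    }
    nodes[[ai]] <- merged
    sizes[ai] <- sizes[ai] + sizes[aj]
    active <- setdiff(active, aj)
  }
  nodes[[active]]
}

#' @export
print.dendro_node <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram node: %d leaves, height %.4g\n",
              length(x$members), x$height))
  cat("leaves:", paste(utils::head(x$members, 8), collapse = ", "),
      if (length(x$members) > 8) "...\n" else "\n")
  invisible(x)
}

#' Leaves and cophenetic distances of a dendrogram
#'
#' `tree_leaves()` returns the sorted leaf labels under a node.
#' `tree_cophenetic()` returns the matrix of cophenetic distances: for each
#' leaf pair, twice the height of their lowest common ancestor. For an
#' ultrametric tree this matrix satisfies the ultrametric inequality
#' `d(i, k) <= max(d(i, j), d(j, k))`.
#'
#' @param node A `dendro_node` as returned by [upgma()].
#' @return `tree_leaves()`: character vector. `tree_cophenetic()`: symmetric
#'   numeric matrix over the leaf labels.
#' @export
tree_leaves <- function(node) node$members

#' @rdname tree_leaves
#' @export
tree_cophenetic <- function(node) {
  leaves <- tree_leaves(node)
  m <- matrix(0, length(leaves), length(leaves), dimnames = list(leaves, leaves))
  fill <- function(nd) {
    if (is.null(nd$children)) return(invisible())
    a <- nd$children[[1]]$members
    b <- nd$children[[2]]$members
    m[a, b] <<- 2 * nd$height
    m[b, a] <<- 2 * nd$height
    fill(nd$children[[1]])
    fill(nd$children[[2]])
  }
  fill(node)
  m
}

#' Two-cluster cut of a dendrogram
#'
#' Removes the root: the leaf sets of its two subtrees are the two major
#' clusters. With the magnitude metric of [rc_distance_matrix()] the two
#' clusters are always contiguous intervals of the sorted |RC| values.
#'
#' @param tree Root `dendro_node` with at least 2 leaves.
#' @return List of two character vectors of leaf labels, ordered as in the
#'   tree.
#' @export
cut_two_clusters <- function(tree) {
  if (is.null(tree$children)) stop("tree has a single leaf; nothing to cut")
  list(tree$children[[1]]$members, tree$children[[2]]$members)
}

#' Cluster |RC| means with bootstrap confidence intervals
#'
#' Summarises each cluster of phosphoproteins by the mean of its members'
#' absolute RC values, with a bias-corrected percentile bootstrap CI
#' ([bc_bootstrap_ci()]) at the given confidence level (default 0.99).
#' Clusters are numbered in decreasing order of mean |RC|, so cluster 1 is
#' the strong-change cluster. The two clusters are called significantly
#' different when their intervals do not overlap. Single-member clusters (and
#' clusters whose members share one |RC| value) get the degenerate interval
#' `(v, v)`.
#'
#' @param clusters List of character vectors of member labels (e.g. from
#'   [cut_two_clusters()]).
#' @param rc_values Named numeric RC vector covering all members.
#' @param conf Confidence level (default 0.99).
#' @param n_boot Bootstrap resamples (default 20000).
#' @param seed Optional integer seed.
#' @return Data frame, one row per cluster: `cluster_id`, `n`, `mean_abs_rc`,
#'   `ci_lower`, `ci_upper`, plus a `members` list column; attribute
#'   `"distinct"` is `TRUE` when no pair of cluster intervals overlaps.
#' @export
cluster_mean_ci <- function(clusters, rc_values, conf = 0.99, n_boot = 20000,
                            seed = NULL) {
  stopifnot(length(clusters) >= 1, all(lengths(clusters) >= 1))
  missing_lab <- setdiff(unlist(clusters), names(rc_values))
  if (length(missing_lab) > 0L) {
    stop("no RC value for member(s): ", paste(missing_lab, collapse = ", "))
  }
  rows <- with_seed(seed, lapply(clusters, function(members) {
    v <- abs(rc_values[members])
    ci <- if (length(v) < 2L || diff(range(v)) == 0) {
      c(cl = unname(v[1L]), cu = unname(v[1L]))
    } else {
      bc_bootstrap_ci(v, conf = conf, n_boot = n_boot)
    }
    data.frame(n = length(v), mean_abs_rc = mean(v),
               ci_lower = ci[["cl"]], ci_upper = ci[["cu"]])
  }))
  out <- do.call(rbind, rows)
  ord <- order(-out$mean_abs_rc)
  out <- out[ord, , drop = FALSE]
  out <- cbind(cluster_id = seq_len(nrow(out)), out)
  out$members <- I(clusters[ord])
  rownames(out) <- NULL
  distinct <- TRUE
  if (nrow(out) >= 2) {
    for (i in seq_len(nrow(out) - 1)) {
      for (j in seq(i + 1, nrow(out))) {
        if (!(out$ci_upper[j] < out$ci_lower[i] || out$ci_upper[i] < out$ci_lower[j])) {
          distinct <- FALSE
        }
      }
    }
  }
  attr(out, "distinct") <- distinct
  out
}

#' Newick serialization of a dendrogram
#'
#' Writes the UPGMA tree in Newick format with branch lengths equal to the
#' height difference between a node and its parent (so root-to-leaf path
#' lengths equal the root height and the tree stays ultrametric in any
#' standard tree viewer). Characters that carry Newick syntax (spaces,
#' parentheses, commas, colons, semicolons, quotes) are replaced by `_` in
#' labels.
#'
#' @param tree Root `dendro_node`.
#' @param digits Significant digits for branch lengths (default 10).
#' @return `as_newick()`: a single Newick string (with trailing `;`).
#' @export
as_newick <- function(tree, digits = 10) {
  clean <- function(l) gsub("[ (),:;'\"\\[\\]]+", "_", l)
  rec <- function(nd, parent_height) {
    bl <- formatC(parent_height - nd$height, digits = digits, format = "g")
    if (is.null(nd$children)) {
      paste0(clean(nd$label), ":", bl)
    } else {
      paste0("(", rec(nd$children[[1]], nd$height), ",",
             rec(nd$children[[2]], nd$height), "):", bl)
    }
  }
  if (is.null(tree$children)) {
    paste0(clean(tree$label), ";")
  } else {
    paste0("(", rec(tree$children[[1]], tree$height), ",",
           rec(tree$children[[2]], tree$height), ");")
  }
}

#' @param path Output file path.
#' @rdname as_newick
#' @export
write_newick <- function(tree, path, digits = 10) {
  writeLines(as_newick(tree, digits = digits), path)
  invisible(path)
}
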