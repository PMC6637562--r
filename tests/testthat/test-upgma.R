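test_that("two leaves merge at half their distance", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tree <- upgma(d)
  expect_equal(tree$height, 0.2)
  expect_equal(tree_leaves(tree), c("A", "B"))
  expect_equal(cut_two_clusters(tree), list("A", "B"))
})

test_that("UPGMA agrees with brute-force recomputation on small matrices", {
  set.seed(41)
  for (n in c(3, 4, 5)) {
    for (rep in 1:20) {
      pts <- runif(n)
      d <- abs(outer(pts, pts, "-")) + as.matrix(stats::dist(matrix(runif(n), n))) * 0.3
      diag(d) <- 0
      dimnames(d) <- list(letters[1:n], letters[1:n])
      tree <- upgma(d)
      expect_equal(tree_cophenetic(tree), brute_upgma_cophenetic(d),
                   tolerance = 1e-12)
    }
  }
})

test_that("UPGMA cophenetic distances match hclust average linkage", {
  set.seed(42)
  pts <- matrix(runif(24), 12)
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(sprintf("P%02d", 1:12), sprintf("P%02d", 1:12))
  mine <- tree_cophenetic(upgma(d))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ref <- as.matrix(stats::cophenetic(hc))
  expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-12)
})

test_that("output is ultrametric and invariant to label permutation", {
  set.seed(43)
  for (rep in 1:10) {
    n <- 8
    d <- as.matrix(stats::dist(matrix(runif(n * 2), n)))
    labs <- sprintf("L%02d", sample(100, n))
    dimnames(d) <- list(labs, labs)
    coph <- tree_cophenetic(upgma(d))
    expect_true(is_ultrametric(coph))
    # permute input rows: same cophenetic structure
    perm <- sample(n)
    coph2 <- tree_cophenetic(upgma(d[perm, perm]))
    expect_equal(coph2[rownames(coph), colnames(coph)], coph)
  }
})

test_that("invalid distance matrices are rejected", {
  d <- matrix(c(0, 1, 2, 0), 2)
  expect_error(upgma(d), "symmetric")
  d2 <- matrix(c(0, -1, -1, 0), 2)
  expect_error(upgma(d2), "non-negative")
})

test_that("RC distance matrix uses |RC| magnitudes by default", {
  rc <- c(A = 0.99, B = -0.78, C = 0.10)
  d <- rc_distance_matrix(rc)
  expect_equal(d["A", "B"], 0.21)  # strong increase ~ strong decrease
  expect_equal(d["B", "C"], 0.68)
  expect_equal(diag(d), c(A = 0, B = 0, C = 0))
  ds <- rc_distance_matrix(rc, metric = "signed")
  expect_equal(ds["A", "B"], 1.77)
})

test_that("two-cluster cut separates bimodal |RC| values and is contiguous", {
  set.seed(44)
  for (rep in 1:10) {
    rc <- c(runif(6, 0.05, 0.15), runif(6, 0.85, 0.95)) *
      sample(c(-1, 1), 12, replace = TRUE)
    names(rc) <- sprintf("S%02d", 1:12)
    clusters <- cut_two_clusters(upgma(rc_distance_matrix(rc)))
    means <- vapply(clusters, function(m) mean(abs(rc[m])), numeric(1))
    hi <- clusters[[which.max(means)]]
    expect_setequal(hi, names(rc)[abs(rc) > 0.5])
    # 1-D metric -> clusters are contiguous intervals of sorted |RC|
    v <- sort(abs(rc))
    idx <- sort(match(sort(abs(rc[clusters[[1]]])), v))
    expect_equal(idx, seq(min(idx), max(idx)))
  }
})

test_that("reference RC values split into the published strong-change cluster", {
  chg <- dfd_reference_changes()
  rc <- setNames(chg$rc, chg$protein)
  clusters <- cut_two_clusters(upgma(rc_distance_matrix(rc)))
  means <- vapply(clusters, function(m) mean(abs(rc[m])), numeric(1))
  hi <- clusters[[which.max(means)]]
  # qualitative check: published membership of the strong cluster (exact
  # membership is not recoverable from rounded RC values)
  expect_true(all(c("MYLPF (1)", "MYLPF (2)", "TNNT1 (1)", "TNNT1 (2)",
                    "TNNT3 (1)", "TNNT3 (2)", "TNNT3 (3)", "TNNT3 (4)",
                    "CAPZA2") %in% hi))
  cs <- cluster_mean_ci(clusters, rc, conf = 0.99, n_boot = 5000, seed = 1)
  expect_true(attr(cs, "distinct"))
  expect_gt(cs$mean_abs_rc[1], 0.7)
})

test_that("cluster mean CIs separate bimodal clusters and handle degeneracy", {
  one <- cluster_mean_ci(list("A"), c(A = 0.7), seed = 1)
  expect_equal(one$ci_lower, 0.7)
  expect_equal(one$ci_upper, 0.7)
  flat <- cluster_mean_ci(list(c("A", "B")), c(A = 0.5, B = -0.5), seed = 1)
  expect_equal(flat$mean_abs_rc, 0.5)
  expect_equal(flat$ci_lower, flat$ci_upper)

  sep <- 0L
  for (s in 1:20) {
    set.seed(800 + s)
    rc <- c(runif(6, 0.05, 0.2), runif(6, 0.8, 0.95))
    names(rc) <- sprintf("S%02d", 1:12)
    cl <- cut_two_clusters(upgma(rc_distance_matrix(rc)))
    cs <- cluster_mean_ci(cl, rc, conf = 0.99, n_boot = 4000, seed = s)
    expect_equal(cs$cluster_id, c(1, 2))
    expect_gte(cs$mean_abs_rc[1], cs$mean_abs_rc[2])  # cluster 1 = strong change
    sep <- sep + attr(cs, "distinct")
  }
  expect_gte(sep / 20, 0.95)
})

test_that("Newick export round-trips through ape with correct path lengths", {
  skip_if_not_installed("ape")
  set.seed(45)
  d <- as.matrix(stats::dist(matrix(runif(12), 6)))
  dimnames(d) <- list(sprintf("S%d", 1:6), sprintf("S%d", 1:6))
  tree <- upgma(d)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, f)
  ph <- ape::read.tree(f)
  expect_setequal(ph$tip.label, sprintf("S%d", 1:6))
  # ultrametric in ape's sense: all root-to-tip distances equal tree height
  depths <- diag(ape::vcv(ph)) + 0  # variance = root-to-tip path length
  expect_equal(unname(depths), rep(tree$height, 6), tolerance = 1e-8)
})
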