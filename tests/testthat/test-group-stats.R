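test_that("group spot counts and unique/shared decomposition", {
  t1 <- make_group_table(k = 4, group = "DFD", pr = c(0.5, 0.4, 0, 0))
  t2 <- make_group_table(k = 4, group = "control", pr = c(0.5, 0, 0.3, 0))
  # pr = 0 creates zero-volume phospho rows; drop them to model absence
  t1 <- t1[!(t1$channel == "phospho" & t1$volume == 0), ]
  t2 <- t2[!(t2$channel == "phospho" & t2$volume == 0), ]
  counts <- spot_group_counts(t1, t2)
  expect_equal(counts$n_reproducible_treated, 4)
  expect_equal(counts$n_phospho_treated, 2)
  expect_equal(counts$n_phospho_control, 2)
  expect_equal(counts$n_shared_phospho, 1)
  expect_equal(counts$n_unique_treated, 1)
  expect_equal(counts$n_unique_control, 1)

  # identical tables -> no unique spots
  same <- spot_group_counts(t1, t1)
  expect_equal(same$n_unique_treated, 0)
  expect_equal(same$n_unique_control, 0)
})

test_that("phospho percentages use one-decimal rounding", {
  expect_equal(phospho_percentage(46, 314), 14.6)
  expect_equal(phospho_percentage(41, 308), 13.3)
  expect_equal(phospho_percentage(0, 10), 0)
  expect_error(phospho_percentage(5, 0))
})

test_that("Fisher exact matches brute-force enumeration on small tables", {
  set.seed(31)
  for (i in 1:40) {
    cells <- as.vector(stats::rmultinom(1, sample(4:12, 1), rep(0.25, 4)))
    tab <- matrix(cells, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_two_tailed(cells[1], cells[3], cells[2], cells[4]),
                 enum_fisher_p(cells[1], cells[3], cells[2], cells[4]),
                 tolerance = 1e-10)
  }
})

test_that("Fisher P is invariant to row/column swaps and in (0, 1]", {
  p <- fisher_exact_two_tailed(46, 268, 41, 267)
  expect_equal(fisher_exact_two_tailed(41, 267, 46, 268), p)
  expect_equal(fisher_exact_two_tailed(268, 46, 267, 41), p)
  expect_gt(p, 0); expect_lte(p, 1)
  expect_equal(fisher_exact_two_tailed(5, 5, 5, 5), 1)
  expect_warning(p0 <- fisher_exact_two_tailed(0, 0, 3, 4), "degenerate")
  expect_equal(p0, 1)
})

test_that("Mann-Whitney matches rank-assignment enumeration when exact", {
  res <- mann_whitney_two_tailed(c(1, 2), c(3, 4))
  expect_equal(res$p, 1 / 3)
  expect_equal(res$p, enum_mw_p(c(1, 2), c(3, 4)))
  set.seed(32)
  for (i in 1:10) {
    x <- sample(100, 3); y <- setdiff(sample(100, 8), x)[1:4]
    expect_equal(mann_whitney_two_tailed(x, y)$p, enum_mw_p(x, y))
  }
})

test_that("Mann-Whitney U identities and degenerate identical samples", {
  x <- c(5, 1, 9, 3); y <- c(7, 2, 8, 4, 6)
  ux <- mann_whitney_two_tailed(x, y)$U
  uy <- mann_whitney_two_tailed(y, x)$U
  expect_equal(ux + uy, length(x) * length(y))  # no ties
  same <- mann_whitney_two_tailed(1:6, 1:6)
  expect_equal(same$U, 18)  # n^2 / 2 with midranks
  expect_gt(same$p, 0.9)
})
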