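test_that("noise-free synthetic data reproduces true fractions exactly", {
  sim <- generate_spot_table(scenario_preset("noise_free"))
  res <- analyze_spot_set(sim$treated, sim$control, n_boot = 500, seed = 3)
  truth <- sim$truth
  d <- merge(res$differential, truth, by = "spot_id")
  expect_equal(d$dpr, d$delta_pr)  # machine-precision recovery
  expect_equal(d$pr_treated, d$fraction_treated)
  # m counts spots with phospho signal in >= 1 group (5 unique + 5 shared)
  expect_equal(res$m, 10)
  expect_equal(res$conf_adjusted, 1 - 0.05 / 10)
  # phospho-negative spots are not evaluable
  expect_true(all(d$significant[d$fraction_treated == 0 &
                                  d$fraction_control == 0] == "not_evaluable"))
})

test_that("replicates with absent phospho rows contribute PR = 0", {
  tab <- make_group_table(k = 2, n_reps = 4, pr = c(0.4, 0.4))
  # S001: phospho missing on replicates 3-4 -> PR values (0.4, 0.4, 0, 0)
  tab <- drop_replicates(tab, "S001", c(3, 4), channels = "phospho")
  prs <- phosphoRate:::pr_replicate_values(tab)
  expect_equal(sort(prs$S001), c(0, 0, 0.4, 0.4))
  expect_equal(prs$S002, rep(0.4, 4))
})

test_that("analysis is deterministic under a fixed seed", {
  sim <- generate_spot_table(scenario_preset("small_recovery", seed = 8))
  r1 <- analyze_spot_set(sim$treated, sim$control, n_boot = 1000, seed = 42)
  r2 <- analyze_spot_set(sim$treated, sim$control, n_boot = 1000, seed = 42)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$differential, r2$differential)
})

test_that("disjoint spot universes are rejected", {
  t1 <- make_group_table(k = 2, group = "DFD")
  t2 <- make_group_table(k = 2, group = "control")
  t2$spot_id <- sub("S00", "X00", t2$spot_id)
  expect_error(analyze_spot_set(t1, t2, n_boot = 100), "not matched")
})

test_that("small recovery scenario flags exactly the truly changed spots", {
  n_seeds <- 50
  hits <- matrix(NA, n_seeds, 20)
  fp <- 0; nulls <- 0
  for (s in seq_len(n_seeds)) {
    sim <- generate_spot_table(scenario_preset("small_recovery", seed = 5000 + s))
    res <- analyze_spot_set(sim$treated, sim$control, n_boot = 2000, seed = s)
    d <- merge(res$differential, sim$truth, by = "spot_id")
    called <- d$significant == "yes"
    hits[s, ] <- called[match(sprintf("S%03d", 1:20), d$spot_id)]
    fp <- fp + sum(called & !d$expected_significant)
    nulls <- nulls + sum(!d$expected_significant)
  }
  # the five 0.8-vs-0 spots are recovered in >= 95% of seeds
  expect_gte(mean(hits[, 1:5]), 0.95)
  # false-positive rate over null spots stays below alpha
  expect_lte(fp / nulls, 0.05)
})

test_that("differential_from_summary matches analyze_spot_set on clean data", {
  sim <- generate_spot_table(scenario_preset("noise_free"))
  res <- analyze_spot_set(sim$treated, sim$control, n_boot = 500, seed = 3)
  s <- res$summary
  gt <- res$groups[["treated"]]
  wide <- merge(
    stats::setNames(s[s$group == gt, c("spot_id", "mean_pr", "ci_lower", "ci_upper")],
                    c("spot_id", "pr_mean_treated", "ci_lower_treated", "ci_upper_treated")),
    stats::setNames(s[s$group != gt, c("spot_id", "mean_pr", "ci_lower", "ci_upper")],
                    c("spot_id", "pr_mean_control", "ci_lower_control", "ci_upper_control")),
    by = "spot_id")
  d2 <- differential_from_summary(wide)
  expect_equal(d2$dpr, res$differential$dpr)
  expect_equal(d2$significant, res$differential$significant)
  expect_equal(d2$rc, res$differential$rc)
})
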