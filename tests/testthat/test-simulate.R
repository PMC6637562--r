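test_that("config validation names the offending field", {
  expect_error(sim_config(0), "n_spots")
  expect_error(sim_config(5, noise_cv = -1), "noise_cv")
  expect_error(sim_config(5, phospho_fractions = 1.2), "phospho_fractions")
  expect_error(sim_config(5, detection_prob = -0.1), "detection_prob")
  expect_error(sim_config(5, phospho_fractions = matrix(0.5, 3, 2)),
               "phospho_fractions")
  expect_error(sim_config(5, n_replicates = 0), "n_replicates")
})

test_that("derived unique-spot fractions reflect the fraction matrix", {
  f <- matrix(0, 10, 2)
  f[1:4, 1] <- 0.5          # 4 treated-unique
  f[5:6, ] <- 0.3           # 2 shared
  f[7, 2] <- 0.2            # 1 control-unique
  cfg <- sim_config(10, phospho_fractions = f)
  expect_equal(cfg$frac_unique_treated, 4 / 6)
  expect_equal(cfg$frac_unique_control, 1 / 3)
})

test_that("noise-free generation reproduces fractions and full detection", {
  cfg <- scenario_preset("noise_free")
  sim <- generate_spot_table(cfg)
  # every spot present on all 4 replicates in both groups
  for (tab in list(sim$treated, sim$control)) {
    tot <- tab[tab$channel == "total", ]
    expect_equal(unname(table(tot$spot_id)), rep(4L, 20), ignore_attr = TRUE)
  }
  # per-replicate P/T equals the true fraction exactly
  tr <- sim$treated
  key <- paste(tr$spot_id, tr$replicate)
  pho <- tr[tr$channel == "phospho", ]
  tot <- tr[tr$channel == "total", ]
  ratio <- pho$volume / tot$volume[match(paste(pho$spot_id, pho$replicate),
                                         paste(tot$spot_id, tot$replicate))]
  truth <- sim$truth$fraction_treated[match(pho$spot_id, sim$truth$spot_id)]
  expect_equal(ratio, truth)
})

test_that("identical seed and config give byte-identical tables", {
  cfg <- scenario_preset("small_recovery", seed = 77)
  s1 <- generate_spot_table(cfg)
  s2 <- generate_spot_table(cfg)
  expect_identical(s1, s2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_spot_table(s1$treated, f1)
  write_spot_table(s2$treated, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed -> different volumes
  s3 <- generate_spot_table(scenario_preset("small_recovery", seed = 78))
  expect_false(identical(s1$treated$volume, s3$treated$volume))
})

test_that("detection dropout produces absent records, not zeros", {
  cfg <- sim_config(50, detection_prob = 0.5, phospho_fractions = 0.4,
                    seed = 9)
  sim <- generate_spot_table(cfg)
  tot <- sim$treated[sim$treated$channel == "total", ]
  expect_lt(nrow(tot), 50 * 4)        # some spot-replicates missing entirely
  expect_true(all(tot$volume > 0))    # never encoded as zero volume
})

test_that("preset dimensions mirror the reference study design", {
  cfg <- scenario_preset("paper_like")
  expect_equal(cfg$n_replicates, 4)
  expect_equal(cfg$n_spots, 314)
  pos_t <- sum(cfg$phospho_fractions[, 1] > 0)
  pos_c <- sum(cfg$phospho_fractions[, 2] > 0)
  expect_equal(pos_t, 46)   # 14.6% of 314
  expect_equal(pos_c, 41)
  expect_true(100 * pos_t / cfg$n_spots > 13 && 100 * pos_t / cfg$n_spots < 16)
  shared <- sum(cfg$phospho_fractions[, 1] > 0 & cfg$phospho_fractions[, 2] > 0)
  expect_equal(shared, 28)
  expect_error(scenario_preset("no_such_scenario"), "valid names")
})

test_that("truth labels are consistent with the configured fractions", {
  cfg <- scenario_preset("paper_like")
  truth <- generate_spot_table(cfg)$truth
  expect_equal(truth$expected_significant,
               abs(truth$fraction_treated - truth$fraction_control) >= 0.1)
  expect_equal(nrow(truth), cfg$n_spots)
})

test_that("stronger true differences are detected at least as often", {
  deltas <- c(0.05, 0.15, 0.4)
  n_seeds <- 15
  rates <- sapply(deltas, function(delta) {
    f <- matrix(0.3, 4, 2)
    f[, 1] <- 0.3 + delta
    hits <- 0
    for (s in seq_len(n_seeds)) {
      cfg <- sim_config(4, phospho_fractions = f, detection_prob = 1,
                        noise_cv = 0.1, gel_factor_sd = 0.05, seed = 300 + s)
      sim <- generate_spot_table(cfg)
      res <- analyze_spot_set(sim$treated, sim$control, n_boot = 2000, seed = s)
      hits <- hits + sum(res$differential$significant == "yes")
    }
    hits / (n_seeds * 4)
  })
  expect_true(all(diff(rates) >= 0))
})
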