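# synthetic_data: determinism, combinatorics, margins, noise statistics.

test_that("generate_series is deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 99)
  g1 <- generate_series(cfg)
  g2 <- generate_series(cfg)
  expect_identical(g1$records, g2$records)
  expect_identical(g1$truth$planted_cliff_pairs, g2$truth$planted_cliff_pairs)
  # a different seed moves the activities
  g3 <- generate_series(synthetic_config(seed = 100))
  expect_false(identical(g1$records$modl_ga, g3$records$modl_ga))
})

test_that("generator does not disturb the session RNG state", {
  set.seed(123); before <- .Random.seed
  invisible(generate_series(synthetic_config(seed = 5)))
  expect_identical(before, .Random.seed)
})

test_that("family/substituent combinatorics determine the record count", {
  g <- generate_series(synthetic_config(n_scaffold_families = 2,
                                        family_size = 6, seed = 1))
  expect_equal(nrow(g$records), 12)
  expect_equal(length(unique(g$truth$chemicals$family)), 2)
  # no planting when the fraction is zero
  g0 <- generate_series(synthetic_config(planted_cliff_fraction = 0,
                                         seed = 2))
  expect_equal(nrow(g0$truth$planted_cliff_pairs), 0)
  expect_equal(length(g0$truth$planted_acg_ids), 0)
})

test_that("the margin invariant rejects under-separated configurations", {
  # the general-use defaults (jump 3, noise 0.2) do not guarantee exact
  # recovery: 3 - 0.3 - 6*0.2 = 1.5 < 2
  expect_error(synthetic_config(noise_sd = 0.2, check_margin = TRUE),
               "margin")
  expect_silent(synthetic_config(noise_sd = 0.1, check_margin = TRUE))
  expect_error(synthetic_config(cliff_jump = 10, noise_sd = 0.4,
                                check_margin = TRUE), "margin")
})

test_that("noise deviations have the half-normal mean absolute deviation", {
  dev <- sascliffs:::truncated_noise(10000, 0.2)
  expect_lt(abs(mean(abs(dev)) / (0.2 * sqrt(2 / pi)) - 1), 0.1)
  expect_true(all(abs(dev) <= 3 * 0.2))        # hard 3-sigma truncation
  # realized pac50 deviations in a generated set come from that noise
  g <- generate_series(synthetic_config(seed = 17, noise_sd = 0.2))
  d <- g$truth$chemicals$pac50 - g$truth$chemicals$pac50_noiseless
  expect_true(all(abs(d) <= 0.6 + 1e-12))
})

test_that("generated tables round-trip through the file reader", {
  g <- generate_series(synthetic_config(n_scaffold_families = 2, seed = 3))
  path <- write_raw_csv(g$records)
  raw <- parse_activity_table(path)
  expect_equal(raw$chem_id, g$records$chem_id)
  expect_equal(raw$modl_ga, g$records$modl_ga)
  expect_equal(raw$hit_call, rep("active", nrow(raw)))
})

test_that("dual-endpoint generation honours requested counts and rejects infeasible ones", {
  dual <- generate_dual_endpoint(synthetic_config(seed = 4),
                                 counts = list(strong = 1, same = 2,
                                               weak = 1))
  tab <- table(dual$truth$pair_labels$label)
  expect_equal(as.integer(tab[c("strong_moa_cliff", "same_moa",
                                "weak_moa_cliff")]),
               c(1L, 2L, 1L))
  expect_error(generate_dual_endpoint(synthetic_config(seed = 4),
                                      counts = list(strong = 20, same = 0,
                                                    weak = 0)),
               "infeasible")
  # empty request: nothing survives the inactive-both filter
  none <- generate_dual_endpoint(synthetic_config(seed = 5),
                                 counts = list(strong = 0, same = 0,
                                               weak = 0),
                                 n_inactive_both = 2)
  expect_equal(nrow(none$truth$pair_labels), 0)
  ds <- filter_active_any(intersect_datasets(curated_records(none$agonists),
                                             curated_records(none$antagonists)))
  expect_equal(nrow(ds), 0)
})

test_that("micro fixtures carry the documented record sets", {
  fx <- micro_fixtures()
  expect_setequal(names(fx), c("mmp_basic", "cresols", "skeleton",
                               "curation"))
  expect_equal(nrow(fx$mmp_basic$records), 4)
  expect_equal(nrow(fx$curation$records), 7)
  std <- standardize_structures(fx$skeleton$records$smiles)
  expect_true(all(std$status == "ok"))
})
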