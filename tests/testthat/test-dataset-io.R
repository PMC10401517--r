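# dataset_io: parsing, standardization, deduplication, curation.

test_that("parse_activity_table reads toy tables and applies the missing-value rule", {
  df <- data.frame(casrn = c("1-1-1", "2-2-2", "3-3-3"),
                   smiles = c("c1ccccc1", "Cc1ccccc1", "CCO"),
                   modl_ga = c("0.5", "", "oops"),
                   hit_c = c(1, 0, 1),
                   endpoint = "agonist",
                   extra = c("x", "y", "z"))
  path <- write_raw_csv(df)
  raw <- parse_activity_table(path, column_map = c(chem_id = "casrn"))
  expect_equal(nrow(raw), 3)
  expect_equal(raw$chem_id, df$casrn)
  expect_equal(raw$modl_ga, c(0.5, NA, NA))         # unparseable -> missing
  expect_equal(raw$hit_call, c("active", "inactive", "active"))
  expect_equal(raw$extra, df$extra)                 # metadata passes through
  # row order preserved
  expect_equal(raw$smiles, df$smiles)
})

test_that("parse_activity_table error contract: missing file and missing column", {
  expect_error(parse_activity_table(tempfile()), "not found")
  df <- data.frame(casrn = "1-1-1", modl_ga = 1)
  path <- write_raw_csv(df)
  expect_error(parse_activity_table(path, column_map = c(chem_id = "casrn")),
               "smiles")
})

test_that("standardize_structure strips salts, flags mixtures and invalids", {
  expect_equal(standardize_structure("CC(=O)O.[Na+]")$canonical_smiles,
               "CC(=O)O")
  expect_equal(standardize_structure("c1ccccc1.c1ccncc1")$reason, "mixture")
  expect_equal(standardize_structure("C1CC")$reason, "invalid")
  expect_equal(standardize_structure("[Na+].[Cl-]")$reason, "invalid")
  # duplicated identical fragments collapse before the mixture test
  expect_equal(standardize_structure("c1ccccc1.c1ccccc1")$canonical_smiles,
               "c1ccccc1")
  # stereo flags are stripped from the canonical key
  expect_equal(standardize_structure("C[C@H](N)c1ccccc1")$canonical_smiles,
               standardize_structure("C[C@@H](N)c1ccccc1")$canonical_smiles)
})

test_that("deduplicate keeps the first record per structure and endpoint", {
  rec <- data.frame(chem_id = c("a", "b", "c"),
                    canonical_smiles = c("c1ccccc1", "c1ccccc1", "c1ccccc1"),
                    endpoint = c("agonist", "agonist", "antagonist"),
                    stringsAsFactors = FALSE)
  out <- deduplicate(rec)
  expect_equal(out$chem_id, c("a", "c"))            # per-endpoint dedup
  expect_equal(attr(out, "removed"),
               data.frame(dropped_id = "b", kept_id = "a",
                          stringsAsFactors = FALSE))
  empty <- rec[0, ]
  expect_equal(nrow(deduplicate(empty)), 0)
})

test_that("remove_linear drops ring-free chemicals only", {
  std <- standardize_structures(c("CCCCCC", "c1ccccc1", "Cc1ccccc1"))
  rec <- data.frame(chem_id = c("hexane", "benzene", "toluene"),
                    canonical_smiles = std$canonical_smiles,
                    n_rings = std$n_rings, stringsAsFactors = FALSE)
  out <- remove_linear(rec)
  expect_equal(out$chem_id, c("benzene", "toluene"))
  expect_equal(attr(out, "removed"), "hexane")
})

test_that("curate applies every rule with correct per-step accounting", {
  fx <- micro_fixtures()$curation
  cur <- curate(fx$records)
  r <- cur$report
  expect_equal(unname(r[c("missing_activity", "mixture", "duplicate",
                          "linear", "invalid")]),
               c(1L, 1L, 1L, 1L, 0L))
  expect_equal(unname(r[["n_curated"]]), 3L)
  expect_setequal(cur$records$name, c("phenol", "toluene",
                                      "anisole hydrochloride"))
  expect_equal(cur$records$pac50, 6 - cur$records$modl_ga)
  # count conservation: input = curated + all drops
  expect_equal(r[["n_input"]],
               r[["n_curated"]] + r[["missing_activity"]] + r[["invalid"]] +
                 r[["mixture"]] + r[["duplicate"]] + r[["linear"]])
  # the log names each dropped record
  expect_equal(nrow(cur$log), 4)
})

test_that("curate is the identity on already-clean input and is idempotent", {
  gen <- generate_series(recovery_config(3, n_families = 2))
  cur1 <- curate(gen$records)
  expect_equal(unname(cur1$report[["n_curated"]]),
               unname(cur1$report[["n_input"]]))
  expect_true(all(cur1$report[c("missing_activity", "invalid", "mixture",
                                "duplicate", "linear")] == 0))
  # idempotence: feed curated records back through as a raw table
  raw2 <- data.frame(chem_id = cur1$records$chem_id,
                     name = cur1$records$name,
                     smiles = cur1$records$canonical_smiles,
                     modl_ga = cur1$records$modl_ga,
                     hit_c = ifelse(cur1$records$hit_call == "active", 1, 0),
                     endpoint = cur1$records$endpoint,
                     stringsAsFactors = FALSE)
  cur2 <- curate(raw2)
  expect_equal(cur2$records$canonical_smiles, cur1$records$canonical_smiles)
  expect_equal(cur2$records$pac50, cur1$records$pac50)
  expect_true(all(cur2$report[c("missing_activity", "invalid", "mixture",
                                "duplicate", "linear")] == 0))
})

test_that("curated records satisfy the record invariants on synthetic fixtures", {
  for (seed in c(11, 12)) {
    cur <- curate(generate_series(recovery_config(seed))$records)
    rec <- cur$records
    expect_true(all(rec$n_rings >= 1))                   # ring present
    expect_equal(rec$pac50, 6 - rec$modl_ga)             # exact formula
    expect_false(any(duplicated(paste(rec$endpoint, rec$canonical_smiles))))
    expect_true(all(nzchar(rec$canonical_smiles)))
  }
})
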