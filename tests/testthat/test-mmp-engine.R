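# mmp_engine: fragmentation, indexing, size restrictions, MMP-cliffs.

test_that("fragment_molecules enumerates hand-derived single cuts", {
  fr <- fragment_molecules("CCc1ccccc1", max_cuts = 1, hydrogen = FALSE)
  # two acyclic C-C single bonds, each giving both orientations
  expect_setequal(
    paste(fr$constant, fr$variable, sep = ">>"),
    c("c1ccc(C[*:1])cc1>>C[*:1]", "C[*:1]>>c1ccc(C[*:1])cc1",
      "c1ccc([*:1])cc1>>CC[*:1]", "CC[*:1]>>c1ccc([*:1])cc1"))
  # ring bonds are never cut: benzene only has hydrogen substitutions
  expect_equal(nrow(fragment_molecules("c1ccccc1", hydrogen = FALSE)), 0)
  frb <- fragment_molecules("c1ccccc1", hydrogen = TRUE)
  expect_equal(frb$variable, "[H][*:1]")
  expect_equal(frb$variable_heavy, 0L)
  # methane: no heavy fragmentation at all
  frm <- fragment_molecules("C", hydrogen = TRUE)
  expect_true(all(frm$variable_heavy == 0))
})

test_that("fragment heavy atoms are conserved on the drug panel", {
  panel <- drug_panel()
  heavy <- standardize_structures(panel$canonical_smiles)$heavy_atoms
  fr <- fragment_molecules(panel, max_cuts = 3, hydrogen = TRUE)
  parent_heavy <- heavy[match(fr$parent_id, panel$chem_id)]
  expect_equal(fr$constant_heavy + fr$variable_heavy, parent_heavy)
  expect_true(all(fr$n_cuts %in% 1:3))
})

test_that("index_mmps finds hand-derived matched pairs and is order-invariant", {
  fx <- micro_fixtures()$mmp_basic$records
  rec <- data.frame(chem_id = fx$chem_id, canonical_smiles = fx$smiles,
                    stringsAsFactors = FALSE)
  fr <- fragment_molecules(rec, max_cuts = 1)
  mm <- index_mmps(fr)
  # toluene/chlorobenzene exchange methyl vs chloro on the phenyl constant
  tc <- mm[mm$id_i == "chlorobenzene" & mm$id_j == "toluene" &
             mm$constant == "c1ccc([*:1])cc1", ]
  expect_equal(nrow(tc), 1)
  expect_setequal(c(tc$frag_i, tc$frag_j), c("Cl[*:1]", "C[*:1]"))
  # all six pairs of the four analogs are matched pairs on that constant
  on_phenyl <- mm[mm$constant == "c1ccc([*:1])cc1", ]
  expect_equal(nrow(on_phenyl), choose(4, 2))
  # identical molecules never pair with themselves
  fr2 <- fragment_molecules(data.frame(
    chem_id = c("x", "y"), canonical_smiles = c("Cc1ccccc1", "Cc1ccccc1"),
    stringsAsFactors = FALSE))
  expect_equal(nrow(index_mmps(fr2)), 0)
  # input order invariance
  shuffled <- fr[rev(seq_len(nrow(fr))), ]
  expect_equal(index_mmps(shuffled), mm)
})

test_that("hydrogen substitution links styrene with beta-nitrostyrene", {
  rec <- data.frame(chem_id = c("styrene", "beta-nitrostyrene"),
                    canonical_smiles = c("C=Cc1ccccc1",
                                         "O=[N+]([O-])C=Cc1ccccc1"),
                    stringsAsFactors = FALSE)
  mm <- index_mmps(fragment_molecules(rec))
  hit <- mm[mm$frag_i == "[H][*:1]" | mm$frag_j == "[H][*:1]", ]
  expect_gte(nrow(hit), 1)
  expect_true("C(=C[*:1])c1ccccc1" %in% hit$constant)
})

test_that("size restrictions implement criteria (i)-(iii) at their boundaries", {
  mk <- function(fi, fj, const, id = "b") data.frame(
    id_i = "a", id_j = id, constant = "K", frag_i = paste0("F", fi),
    frag_j = paste0("G", fj), frag_i_heavy = fi, frag_j_heavy = fj,
    constant_heavy = const, n_cuts = 1L, stringsAsFactors = FALSE)
  expect_equal(nrow(apply_size_restrictions(mk(13, 5, 26))), 1)  # all bounds met
  expect_equal(nrow(apply_size_restrictions(mk(14, 6, 28))), 0)  # (iii): 14 > 13
  expect_equal(nrow(apply_size_restrictions(mk(12, 3, 30))), 0)  # (i): diff 9 > 8
  expect_equal(nrow(apply_size_restrictions(mk(6, 5, 11))), 0)   # (ii): 11 < 12
  expect_equal(nrow(apply_size_restrictions(mk(0, 4, 8))), 1)    # H frag: (ii) vacuous for 0
})

test_that("criterion (iv) picks the least heavy-atom-difference transformation", {
  two <- rbind(
    data.frame(id_i = "a", id_j = "b", constant = "K1", frag_i = "F1",
               frag_j = "G1", frag_i_heavy = 5L, frag_j_heavy = 2L,
               constant_heavy = 30L, n_cuts = 1L),   # diff 3
    data.frame(id_i = "a", id_j = "b", constant = "K2", frag_i = "F2",
               frag_j = "G2", frag_i_heavy = 4L, frag_j_heavy = 3L,
               constant_heavy = 30L, n_cuts = 2L))   # diff 1 -> selected
  sel <- apply_size_restrictions(two)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$constant, "K2")
})

test_that("restriction invariants hold on a synthetic analog series", {
  gen <- generate_series(recovery_config(31, n_families = 3))
  rec <- curated_records(gen$records)
  mm <- index_mmps(fragment_molecules(rec))
  res <- apply_size_restrictions(mm)
  expect_false(any(duplicated(pair_key(res))))          # <= 1 per pair
  expect_true(all(abs(res$frag_i_heavy - res$frag_j_heavy) <= 8))
  expect_true(all(pmax(res$frag_i_heavy, res$frag_j_heavy) <= 13))
  expect_true(all(res$constant_heavy >= 2 * res$frag_i_heavy))
  expect_true(all(res$constant_heavy >= 2 * res$frag_j_heavy))
  # monotone chain: cliffs subset restricted subset indexed
  cl <- find_mmp_cliffs(res, rec)
  expect_true(all(pair_key(cl$cliffs) %in% pair_key(res)))
  expect_true(all(pair_key(res) %in% pair_key(mm)))
})

test_that("find_mmp_cliffs applies the >= 2 threshold and names missing chemicals", {
  res <- data.frame(id_i = c("a", "c"), id_j = c("b", "d"),
                    constant = "K", frag_i = "F", frag_j = "G",
                    frag_i_heavy = 1L, frag_j_heavy = 1L,
                    constant_heavy = 10L, n_cuts = 1L,
                    stringsAsFactors = FALSE)
  rec <- data.frame(chem_id = c("a", "b", "c", "d"),
                    pac50 = c(6.09, 4.00, 5.00, 3.01),
                    stringsAsFactors = FALSE)
  out <- find_mmp_cliffs(res, rec)
  expect_equal(out$mmps$activity_diff, c(2.09, 1.99))
  expect_equal(out$mmps$is_cliff, c(TRUE, FALSE))       # 1.99 is below >= 2
  expect_equal(nrow(out$cliffs), 1)
  expect_error(find_mmp_cliffs(res, rec[-1, ]), "a")
})

test_that("compare_with_sas reports overlap without assuming the subset relation", {
  a <- data.frame(id_i = c("a", "c"), id_j = c("b", "d"))
  b <- data.frame(id_i = c("e"), id_j = c("f"))
  expect_equal(compare_with_sas(a, b)$n_intersection, 0)
  same <- compare_with_sas(a, a)
  expect_equal(same$n_intersection, 2)
  expect_true(same$mmp_subset_of_sas)
  expect_false(compare_with_sas(a, b)$mmp_subset_of_sas)
})

test_that("fragmentation and indexing match the reference MMP implementation", {
  panel <- drug_panel()
  frags <- fragment_molecules(panel, max_cuts = 3, hydrogen = FALSE)
  res <- run_mmpa_oracle(panel, frags, max_cuts = 3)
  for (r in res) {
    expect_true(isTRUE(r$match),
                info = paste0(r$id, " missing: ",
                              paste(unlist(r$missing_from_mine),
                                    collapse = " ; "),
                              " extra: ",
                              paste(unlist(r$extra_in_mine),
                                    collapse = " ; ")))
  }
})
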