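# cliff_classifier: scaffolds, skeletons, R-groups, the 7-type decision tree.

test_that("compute_scaffold prunes side chains and keeps linkers", {
  expect_equal(compute_scaffold("Cc1ccccc1"), "c1ccccc1")
  expect_equal(compute_scaffold("c1ccccc1CCc1ccccc1"),
               "c1ccc(CCc2ccccc2)cc1")
  expect_equal(compute_scaffold("Cc1ccc(O)cc1"), "c1ccccc1")
  expect_error(compute_scaffold("CCCCCC"), "acyclic")
})

test_that("compute_cyclic_skeleton keeps only ring topology", {
  expect_equal(compute_cyclic_skeleton("c1ccncc1"), "C1CCCCC1")
  expect_equal(compute_cyclic_skeleton("c1ccccc1"), "C1CCCCC1")
  expect_equal(compute_cyclic_skeleton("c1ccc(-c2ccccc2)cc1"),
               "C1CCC(C2CCCCC2)CC1")
})

test_that("decompose_rgroups separates scaffold and substituents", {
  dec <- decompose_rgroups(c("Cc1ccc(O)cc1", "c1ccccc1", "Cc1ccccc1O"))
  expect_equal(dec[[1]]$rgroups, c("*C", "*O"))          # para-cresol
  expect_equal(dec[[2]]$rgroups, character())            # bare benzene
  expect_equal(dec[[1]]$rgroups, dec[[3]]$rgroups)       # ortho: same groups
  expect_false(dec[[1]]$scaffold_sig == dec[[3]]$scaffold_sig)  # different sites
  expect_equal(dec[[1]]$scaffold, dec[[3]]$scaffold)
})

test_that("classify_from_comparisons yields exactly one of 7 labels for every combination", {
  labels <- c("chirality", "topology", "r_group", "scaffold",
              "scaffold_topology", "scaffold_r_group", "unclassified")
  seen <- character()
  for (sc in c(TRUE, FALSE)) for (sk in c(TRUE, FALSE))
    for (rg in c(TRUE, FALSE)) for (tp in c(TRUE, FALSE, NA)) {
      lab <- classify_from_comparisons(sc, sk, rg, tp)
      expect_length(lab, 1)
      expect_true(lab %in% labels)
      seen <- union(seen, lab)
    }
  expect_setequal(seen, labels)   # every label reachable
  # the documented mapping for the reachable comparison outcomes
  expect_equal(classify_from_comparisons(TRUE, TRUE, TRUE, TRUE), "chirality")
  expect_equal(classify_from_comparisons(TRUE, TRUE, TRUE, FALSE), "topology")
  expect_equal(classify_from_comparisons(TRUE, TRUE, FALSE, NA), "r_group")
  expect_equal(classify_from_comparisons(FALSE, TRUE, TRUE, TRUE), "scaffold")
  expect_equal(classify_from_comparisons(FALSE, TRUE, TRUE, FALSE),
               "scaffold_topology")
  expect_equal(classify_from_comparisons(FALSE, TRUE, FALSE, NA),
               "scaffold_r_group")
  expect_equal(classify_from_comparisons(FALSE, FALSE, NA, NA),
               "unclassified")
})

test_that("classify_pair reproduces the hand-derived micro fixtures", {
  smiles <- c(ocresol = "Cc1ccccc1O", pcresol = "Cc1ccc(O)cc1",
              pyridine = "c1ccncc1", benzene = "c1ccccc1",
              toluene = "Cc1ccccc1", pic4 = "Cc1ccncc1", pic3 = "Cc1cccnc1",
              chlorobenzene = "Clc1ccccc1",
              isoproterenol = "CC(C)NCC(O)c1ccc(O)c(O)c1",
              epinephrine = "CNCC(O)c1ccc(O)c(O)c1",
              naphthalene = "c1ccc2ccccc2c1")
  dec <- decompose_rgroups(unname(smiles), names(smiles))
  names(dec) <- names(smiles)
  lab <- function(i, j) classify_pair(dec[[i]], dec[[j]])$label
  expect_equal(lab("ocresol", "pcresol"), "topology")
  expect_equal(lab("pyridine", "benzene"), "scaffold")
  expect_equal(lab("toluene", "pic4"), "scaffold")       # same site pattern
  expect_equal(lab("pic4", "pic3"), "topology")          # site moved
  expect_equal(lab("toluene", "chlorobenzene"), "r_group")
  expect_equal(lab("isoproterenol", "epinephrine"), "r_group")
  expect_equal(lab("benzene", "naphthalene"), "unclassified")
  expect_equal(lab("toluene", "toluene"), "chirality")   # graph-identical pair
  # symmetry over all fixture pairs
  ids <- names(smiles)
  for (k in 1:15) {
    ij <- sample(ids, 2)
    expect_equal(lab(ij[1], ij[2]), lab(ij[2], ij[1]))
  }
})

test_that("stereoisomers land in the chirality class", {
  dec <- decompose_rgroups(c("C[C@H](O)c1ccccc1", "C[C@@H](O)c1ccccc1"))
  expect_equal(classify_pair(dec[[1]], dec[[2]])$label, "chirality")
})

test_that("scaffold equality implies skeleton equality across fixtures", {
  smiles <- c(drug_panel()$canonical_smiles, "Cc1ccccc1O", "Cc1ccc(O)cc1")
  dec <- decompose_rgroups(smiles)
  scaff <- vapply(dec, function(d) d$scaffold, "")
  skel <- vapply(dec, function(d) d$skeleton, "")
  for (i in seq_along(dec)) for (j in seq_along(dec)) {
    if (scaff[i] == scaff[j]) expect_equal(skel[i], skel[j])
  }
})

test_that("classify_cliffs labels a cliff table and attaches the histogram", {
  rec <- data.frame(
    chem_id = c("ocresol", "pcresol", "toluene", "chlorobenzene"),
    canonical_smiles = c("Cc1ccccc1O", "Cc1ccc(O)cc1", "Cc1ccccc1",
                         "Clc1ccccc1"),
    stringsAsFactors = FALSE)
  cliffs <- data.frame(id_i = c("ocresol", "chlorobenzene"),
                       id_j = c("pcresol", "toluene"),
                       stringsAsFactors = FALSE)
  out <- classify_cliffs(cliffs, rec)
  expect_equal(out$label, c("topology", "r_group"))
  h <- attr(out, "histogram")
  expect_equal(sum(h), nrow(cliffs))                # histogram sums to cliffs
  expect_equal(as.integer(h[c("topology", "r_group")]), c(1L, 1L))
  expect_error(classify_cliffs(data.frame(id_i = "zz", id_j = "toluene"),
                               rec), "zz")
})
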