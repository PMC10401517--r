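# Shared fixtures and small helpers for the test suite. Everything is built
# in code; no binary fixtures.

# Configuration satisfying the exact planted-cliff separation margin
# (cliff_jump 3, effects +-0.15, truncated noise sd 0.1:
# 3 - 0.3 - 0.6 = 2.1 >= 2 and 0.3 + 0.6 = 0.9 < 2).
recovery_config <- function(seed, n_families = 4, family_size = 6) {
  synthetic_config(n_scaffold_families = n_families,
                   family_size = family_size,
                   noise_sd = 0.1, seed = seed, check_margin = TRUE)
}

curated_records <- function(raw) curate(raw)$records

write_raw_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

pair_key <- function(df) {
  if (nrow(df) == 0) return(character())
  paste(pmin(df$id_i, df$id_j), pmax(df$id_i, df$id_j), sep = "|")
}

# Small drug-like molecule panel used for property tests and the MMP oracle.
drug_panel <- function() {
  data.frame(
    chem_id = c("aspirin", "ibuprofen", "caffeine", "toluene",
                "ethylbenzene", "styrene", "beta-nitrostyrene", "anisole",
                "paracetamol", "chlorobenzene", "naproxen", "benzamide",
                "phenol", "pyridine", "quinoline", "indane", "benzofuran",
                "acetophenone", "benzonitrile", "cumene"),
    canonical_smiles = c(
      "CC(=O)Oc1ccccc1C(=O)O", "CC(C)Cc1ccc(C(C)C(=O)O)cc1",
      "Cn1c(=O)c2c(ncn2C)n(C)c1=O", "Cc1ccccc1", "CCc1ccccc1",
      "C=Cc1ccccc1", "O=[N+]([O-])C=Cc1ccccc1", "COc1ccccc1",
      "CC(=O)Nc1ccc(O)cc1", "Clc1ccccc1",
      "COc1ccc2cc(C(C)C(=O)O)ccc2c1", "NC(=O)c1ccccc1", "Oc1ccccc1",
      "c1ccncc1", "c1ccc2ncccc2c1", "C1Cc2ccccc2C1", "c1ccc2occc2c1",
      "CC(=O)c1ccccc1", "N#Cc1ccccc1", "CC(C)c1ccccc1"),
    stringsAsFactors = FALSE)
}

# Independent oracle for the rdMMPA comparison: runs the reference
# fragmenter and label-normalizes both sides (see oracle_mmpa.py).
run_mmpa_oracle <- function(mols, frags, max_cuts = 3) {
  req <- list(
    records = lapply(seq_len(nrow(mols)), function(i)
      list(id = mols$chem_id[i], smiles = mols$canonical_smiles[i])),
    max_cuts = max_cuts,
    mine = lapply(seq_len(nrow(frags)), function(i)
      list(id = frags$parent_id[i], constant = frags$constant[i],
           variable = frags$variable[i], n_cuts = frags$n_cuts[i])))
  fi <- tempfile(fileext = ".json")
  fo <- tempfile(fileext = ".json")
  on.exit(unlink(c(fi, fo)), add = TRUE)
  jsonlite::write_json(req, fi, auto_unbox = TRUE, digits = NA)
  script <- testthat::test_path("oracle_mmpa.py")
  status <- system2("python", c(shQuote(script), shQuote(fi), shQuote(fo)))
  stopifnot(identical(status, 0L))
  jsonlite::fromJSON(fo, simplifyVector = FALSE)$result
}
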