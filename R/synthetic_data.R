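# Seeded synthetic chemical-activity datasets with planted ground truth.
#
# The generator emulates the shape of a curated screening dataset: scaffold
# families (analog series sharing a large core) decorated with small
# substituents, additive substituent effects on the pAC50 scale, Gaussian
# noise, and planted 100-fold-plus activity jumps (cliffs). Family cores were
# chosen once so that, over the whole substituent library at 2048-bit ECFP4,
# every within-family pair has Tanimoto > 0.35 and every cross-family pair
# has Tanimoto < 0.35; planted-cliff ground truth is therefore pure
# combinatorics over families.

# name = family, value = SMILES template with one aromatic substitution slot
synthetic_family_templates <- c(
  steroid    = "CC12CCC3c4ccc(%s)cc4CCC3C1CCC2O",
  glucoside  = "OCC1OC(Oc2ccc(%s)cc2)C(O)C(O)C1O",
  spiroamine = "CN1CCC2(CCC(%s)CC2)c2ccccc21",
  pyrazole   = "Cn1nc(C(C)(C)C)cc1-c1ccc(%s)cc1",
  flavone    = "O=c1cc(-c2ccccc2)oc2cc(%s)ccc12",
  sulfolane  = "O=S1(=O)CCC(c2ccc(%s)cc2)C1",
  quinpip    = "CN1CCN(c2ccc(%s)cn2)CC1",
  binaph     = "c1ccc2c(-c3ccc4ccccc4c3)c(%s)ccc2c1",
  tetralone  = "O=C1CCCc2cc(%s)ccc21",
  indole     = "Cc1[nH]c2ccc(%s)cc2c1C"
)

# R-group library; "[*][H]" is the unsubstituted parent
synthetic_substituents <- c("[*][H]", "[*]C", "[*]CC", "[*]Cl", "[*]Br",
                            "[*]F", "[*]O", "[*]OC", "[*]N", "[*]C#N")

build_family_smiles <- function(template, substituent) {
  body <- sub("^\\[\\*\\]", "", substituent)
  if (body == "[H]" || body == "") {
    sub("(%s)", "", template, fixed = TRUE)
  } else {
    sprintf(template, body)
  }
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# noise truncated at +-3 sd so separation guarantees are hard, not
# probabilistic
truncated_noise <- function(n, sd) {
  if (sd == 0) return(rep(0, n))
  pmin(pmax(stats::rnorm(n, 0, sd), -3 * sd), 3 * sd)
}

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe a plausible screening world: family base potencies
#' between pAC50 4 and 7 (AC50 100 uM to 0.1 uM), substituent effects within
#' +-0.15 log units, assay noise 0.2 log units, planted cliff jumps of 3 log
#' units. For exact planted-cliff recovery (`check_margin = TRUE`) the
#' separation condition `cliff_jump - effect_range - 6*noise_sd >=
#' act_threshold` and `effect_range + 6*noise_sd < act_threshold` must hold
#' (noise is truncated at three standard deviations), which requires a
#' smaller `noise_sd` than the general-use default.
#'
#' @param n_scaffold_families Number of analog-series families (max 10).
#' @param family_size Analogs per family (max 10).
#' @param substituent_library R-group SMILES with attachment wildcards.
#' @param base_pac50_range Family base-potency interval (pAC50).
#' @param cliff_jump Planted activity jump in log units; default 3.
#' @param noise_sd Gaussian noise SD in log units; default 0.2.
#' @param planted_cliff_fraction Fraction of families receiving one jumped
#'   member; default 0.5.
#' @param effect_halfwidth Half-width of the uniform substituent-effect
#'   distribution; default 0.15.
#' @param seed Integer seed; all randomness is local to the generator.
#' @param check_margin Enforce the exact-recovery separation condition.
#' @param act_threshold,sim_threshold Thresholds the planted truth is
#'   guaranteed against; defaults 2 and 0.35.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_scaffold_families = 4, family_size = 6,
                             substituent_library = synthetic_substituents,
                             base_pac50_range = c(4, 7),
                             cliff_jump = 3.0, noise_sd = 0.2,
                             planted_cliff_fraction = 0.5,
                             effect_halfwidth = 0.15,
                             seed = 1L, check_margin = FALSE,
                             act_threshold = 2.0, sim_threshold = 0.35) {
  stopifnot(n_scaffold_families >= 1,
            n_scaffold_families <= length(synthetic_family_templates),
            family_size >= 2, family_size <= length(substituent_library),
            length(base_pac50_range) == 2, cliff_jump > 0, noise_sd >= 0,
            planted_cliff_fraction >= 0, planted_cliff_fraction <= 1,
            effect_halfwidth >= 0, is.numeric(seed))
  cfg <- structure(list(
    n_scaffold_families = as.integer(n_scaffold_families),
    family_size = as.integer(family_size),
    substituent_library = substituent_library,
    base_pac50_range = base_pac50_range,
    cliff_jump = cliff_jump, noise_sd = noise_sd,
    planted_cliff_fraction = planted_cliff_fraction,
    effect_halfwidth = effect_halfwidth,
    seed = as.integer(seed), check_margin = check_margin,
    act_threshold = act_threshold, sim_threshold = sim_threshold
  ), class = "synthetic_config")
  if (check_margin) {
    effect_range <- 2 * effect_halfwidth
    if (cliff_jump - effect_range - 6 * noise_sd < act_threshold ||
        effect_range + 6 * noise_sd >= act_threshold) {
      stop("config violates the planted-cliff separation margin: need ",
           "cliff_jump - effect_range - 6*noise_sd >= act_threshold and ",
           "effect_range + 6*noise_sd < act_threshold", call. = FALSE)
    }
  }
  cfg
}

#' Generate a single-endpoint analog-series dataset with planted cliffs
#'
#' For each scaffold family, enumerates `family_size` analogs from the
#' substituent library and assigns `pac50 = family base + substituent effect
#' + truncated Gaussian noise`; in a `planted_cliff_fraction` of families one
#' member additionally receives a `cliff_jump`. The emitted table has the raw
#' input schema (`chem_id`, `name`, `smiles`, `modl_ga = 6 - pac50`, `hit_c`,
#' `endpoint`) so it round-trips through [parse_activity_table()] and
#' [curate()]. Ground truth records the planted cliff pairs (every
#' jumped/unjumped pair within a jumped family), the planted ACGs (jumped
#' chemicals with at least 5 partners), the within-family matched pairs, and
#' per-chemical noiseless and realized activities.
#'
#' @param config A [synthetic_config()] object.
#' @param endpoint Endpoint label stamped on the table; default `"agonist"`.
#' @return List with `records` (the raw-schema data.frame) and `truth`.
#' @export
generate_series <- function(config = synthetic_config(),
                            endpoint = "agonist") {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    fams <- names(synthetic_family_templates)[seq_len(config$n_scaffold_families)]
    subs <- config$substituent_library[seq_len(config$family_size)]
    n_jump <- round(config$planted_cliff_fraction * length(fams))
    jump_fams <- if (n_jump > 0) sort(sample(fams, n_jump)) else character()

    rows <- list()
    truth_rows <- list()
    for (fi in seq_along(fams)) {
      fam <- fams[fi]
      base <- stats::runif(1, config$base_pac50_range[1],
                           config$base_pac50_range[2])
      effects <- stats::runif(length(subs), -config$effect_halfwidth,
                              config$effect_halfwidth)
      noise <- truncated_noise(length(subs), config$noise_sd)
      jumped_member <- if (fam %in% jump_fams)
        sample(seq_along(subs), 1) else NA_integer_
      ids <- sprintf("SYN-%02d-%02d", fi, seq_along(subs))
      pac50_true <- base + effects
      pac50 <- pac50_true + noise
      if (!is.na(jumped_member)) {
        pac50_true[jumped_member] <- pac50_true[jumped_member] +
          config$cliff_jump
        pac50[jumped_member] <- pac50[jumped_member] + config$cliff_jump
      }
      smiles <- vapply(subs, function(s)
        build_family_smiles(synthetic_family_templates[[fam]], s), "")
      rows[[fi]] <- data.frame(
        chem_id = ids,
        name = sprintf("%s analog %d", fam, seq_along(subs)),
        smiles = smiles,
        modl_ga = 6 - pac50,
        hit_c = 1L,
        endpoint = endpoint,
        stringsAsFactors = FALSE
      )
      truth_rows[[fi]] <- data.frame(
        chem_id = ids, family = fam, substituent = subs,
        pac50_noiseless = pac50_true, pac50 = pac50,
        jumped = seq_along(subs) %in% jumped_member,
        stringsAsFactors = FALSE
      )
    }
    records <- rbind_rows(rows)
    chem_truth <- rbind_rows(truth_rows)

    pair_rows <- lapply(split(chem_truth, chem_truth$family), function(ft) {
      if (!any(ft$jumped)) return(NULL)
      jid <- ft$chem_id[ft$jumped]
      others <- ft$chem_id[!ft$jumped]
      data.frame(id_i = pmin(jid, others), id_j = pmax(jid, others),
                 stringsAsFactors = FALSE)
    })
    planted_cliffs <- rbind_rows(pair_rows)
    if (is.null(planted_cliffs)) {
      planted_cliffs <- data.frame(id_i = character(), id_j = character(),
                                   stringsAsFactors = FALSE)
    }
    cliff_counts <- table(c(planted_cliffs$id_i, planted_cliffs$id_j))
    acg_ids <- sort(names(cliff_counts)[cliff_counts >= 5 &
                                          names(cliff_counts) %in%
                                          chem_truth$chem_id[chem_truth$jumped]])
    mmp_rows <- lapply(split(chem_truth, chem_truth$family), function(ft) {
      if (nrow(ft) < 2) return(NULL)
      cmb <- utils::combn(sort(ft$chem_id), 2)
      data.frame(id_i = cmb[1, ], id_j = cmb[2, ], family = ft$family[1],
                 stringsAsFactors = FALSE)
    })
    planted_mmps <- rbind_rows(mmp_rows)
    if (is.null(planted_mmps)) {
      planted_mmps <- data.frame(id_i = character(), id_j = character(),
                                 family = character(),
                                 stringsAsFactors = FALSE)
    }

    list(records = records,
         truth = list(chemicals = chem_truth,
                      planted_cliff_pairs = planted_cliffs,
                      planted_acg_ids = acg_ids,
                      planted_mmp_pairs = planted_mmps,
                      jumped_families = jump_fams,
                      config = config))
  })
}

#' Generate dual-endpoint tables with planted MOA-pair labels
#'
#' Builds one two-analog family per requested pair; the two analogs of a
#' family are structurally similar (same core) while all cross-family pairs
#' are dissimilar, so the similar-pair set equals the planted set exactly.
#' Hit-call tuples realize the requested label: strong MOA-cliff =
#' `(active, inactive)` vs `(inactive, active)`; same MOA = `(active,
#' active)` twice; weak MOA-cliff = `(active, active)` vs `(active,
#' inactive)`. `n_inactive_both` additional singleton chemicals carry
#' `(inactive, inactive)` and must be removed by [filter_active_any()].
#'
#' @param config A [synthetic_config()] object (seed and activity parameters
#'   are reused).
#' @param counts Named list/vector with requested `strong`, `same`, `weak`
#'   pair counts. The total must not exceed the number of available family
#'   cores (10 minus `n_inactive_both` singleton cores).
#' @param n_inactive_both Number of planted inactive-in-both chemicals.
#' @return List with `agonists`, `antagonists` (raw-schema data.frames) and
#'   `truth` (planted labels per pair and per-chemical tuples).
#' @export
generate_dual_endpoint <- function(config = synthetic_config(),
                                   counts = list(strong = 2, same = 3,
                                                 weak = 3),
                                   n_inactive_both = 2) {
  stopifnot(inherits(config, "synthetic_config"))
  counts <- lapply(counts, as.integer)
  stopifnot(all(c("strong", "same", "weak") %in% names(counts)),
            all(unlist(counts) >= 0), n_inactive_both >= 0)
  n_pairs <- counts$strong + counts$same + counts$weak
  n_fams <- n_pairs + n_inactive_both
  if (n_fams > length(synthetic_family_templates)) {
    stop("requested label counts are infeasible: need ", n_fams,
         " distinct family cores but only ",
         length(synthetic_family_templates), " are available", call. = FALSE)
  }
  with_seed(config$seed + 1L, {
    labels <- c(rep("strong_moa_cliff", counts$strong),
                rep("same_moa", counts$same),
                rep("weak_moa_cliff", counts$weak))
    tuples <- list(
      strong_moa_cliff = list(c("active", "inactive"),
                              c("inactive", "active")),
      same_moa = list(c("active", "active"), c("active", "active")),
      weak_moa_cliff = list(c("active", "active"), c("active", "inactive"))
    )
    fams <- names(synthetic_family_templates)
    rows <- list(); truth_pairs <- list(); chems <- list()
    for (k in seq_along(labels)) {
      fam <- fams[k]
      ids <- sprintf("MOA-%02d-%d", k, 1:2)
      subs <- config$substituent_library[2:3]  # two distinct real R-groups
      smiles <- vapply(subs, function(s)
        build_family_smiles(synthetic_family_templates[[fam]], s), "")
      tup <- tuples[[labels[k]]]
      pac <- stats::runif(2, config$base_pac50_range[1],
                          config$base_pac50_range[2])
      chems[[k]] <- data.frame(
        chem_id = ids, name = paste(fam, "moa analog", 1:2),
        smiles = smiles, pac50 = pac,
        agonist_hit = c(tup[[1]][1], tup[[2]][1]),
        antagonist_hit = c(tup[[1]][2], tup[[2]][2]),
        stringsAsFactors = FALSE
      )
      truth_pairs[[k]] <- data.frame(id_i = min(ids), id_j = max(ids),
                                     label = labels[k],
                                     stringsAsFactors = FALSE)
    }
    for (k in seq_len(n_inactive_both)) {
      fam <- fams[n_pairs + k]
      id <- sprintf("MOA-X%02d-1", k)
      chems[[n_pairs + k]] <- data.frame(
        chem_id = id, name = paste(fam, "inactive-both"),
        smiles = build_family_smiles(synthetic_family_templates[[fam]],
                                     config$substituent_library[2]),
        pac50 = stats::runif(1, config$base_pac50_range[1],
                             config$base_pac50_range[2]),
        agonist_hit = "inactive", antagonist_hit = "inactive",
        stringsAsFactors = FALSE
      )
    }
    chems <- rbind_rows(chems)
    truth <- rbind_rows(truth_pairs)
    if (is.null(truth)) {
      truth <- data.frame(id_i = character(), id_j = character(),
                          label = character(), stringsAsFactors = FALSE)
    }
    as_table <- function(endpoint, hit) data.frame(
      chem_id = chems$chem_id, name = chems$name, smiles = chems$smiles,
      modl_ga = 6 - chems$pac50,
      hit_c = ifelse(hit == "active", 1L, 0L),
      endpoint = endpoint, stringsAsFactors = FALSE)
    list(agonists = as_table("agonist", chems$agonist_hit),
         antagonists = as_table("antagonist", chems$antagonist_hit),
         truth = list(pair_labels = truth, chemicals = chems,
                      config = config))
  })
}

#' Hand-curated micro fixtures with worked answers
#'
#' Tiny named molecule sets whose expected results were derived by hand and
#' are frozen in the package tests: `mmp_basic` (benzene/toluene/
#' chlorobenzene/ethylbenzene analog set), `cresols` (ortho- vs para-cresol,
#' the attachment-topology fixture), `skeleton` (pyridine and benzene share a
#' cyclic skeleton), and `curation` (a raw table exercising every curation
#' drop rule).
#'
#' @return Named list; each element has `records` (data.frame) and `notes`.
#' @export
micro_fixtures <- function() {
  list(
    mmp_basic = list(
      records = data.frame(
        chem_id = c("benzene", "toluene", "chlorobenzene", "ethylbenzene"),
        smiles = c("c1ccccc1", "Cc1ccccc1", "Clc1ccccc1", "CCc1ccccc1"),
        stringsAsFactors = FALSE),
      notes = paste("all six pairs are single-cut matched pairs on the",
                    "attachment-labelled benzene constant")),
    cresols = list(
      records = data.frame(
        chem_id = c("o-cresol", "p-cresol"),
        smiles = c("Cc1ccccc1O", "Cc1ccc(O)cc1"),
        stringsAsFactors = FALSE),
      notes = paste("same scaffold (benzene) and R-groups {methyl,",
                    "hydroxyl}, different attachment pattern: a topology",
                    "cliff")),
    skeleton = list(
      records = data.frame(
        chem_id = c("pyridine", "benzene"),
        smiles = c("c1ccncc1", "c1ccccc1"),
        stringsAsFactors = FALSE),
      notes = "different scaffolds, one shared cyclohexane skeleton"),
    curation = list(
      records = data.frame(
        chem_id = sprintf("CUR-%d", 1:7),
        name = c("phenol", "toluene", "anisole hydrochloride",
                 "benzene-pyridine mixture", "phenol duplicate",
                 "hexane", "no activity"),
        smiles = c("Oc1ccccc1", "Cc1ccccc1", "COc1ccccc1.Cl",
                   "c1ccccc1.c1ccncc1", "c1ccc(O)cc1", "CCCCCC",
                   "c1ccsc1"),
        modl_ga = c(0.5, 1.2, -0.3, 0.8, 2.0, 1.1, NA),
        hit_c = c(1, 1, 1, 0, 1, 1, 1),
        endpoint = "agonist",
        stringsAsFactors = FALSE),
      notes = paste("expected survivors: phenol, toluene, anisole;",
                    "drops: 1 missing activity, 1 mixture, 1 duplicate,",
                    "1 linear"))
  )
}
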