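# Seven-type structural classification of activity cliffs from scaffolds,
# cyclic skeletons, R-groups and R-group topology.

cliff_labels <- c("chirality", "topology", "r_group", "scaffold",
                  "scaffold_topology", "scaffold_r_group", "unclassified")

#' Decompose molecules into scaffold, cyclic skeleton and R-groups
#'
#' Computes, per molecule: the Bemis-Murcko scaffold (ring systems plus
#' linkers, canonical SMILES); the cyclic skeleton (scaffold with every heavy
#' atom carbon and every bond single - ring topology only); the multiset of
#' R-group fragments (attachment wildcard included, stereo-stripped); and two
#' attachment-topology signatures: the scaffold and the skeleton decorated
#' with one labelled attachment point per R-group (labels encode which
#' R-group sits where). Signatures are canonical SMILES, so comparisons are
#' automatically up to graph automorphism.
#'
#' @param smiles Character vector of canonical SMILES (must contain a ring).
#' @param ids Optional identifiers; default the SMILES themselves.
#' @return A list of `scaffold_decomposition` objects (fields `chem_id`,
#'   `scaffold`, `skeleton`, `rgroups`, `scaffold_sig`, `skeleton_sig`,
#'   `n_attachments`).
#' @export
decompose_rgroups <- function(smiles, ids = smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1,
            length(ids) == length(smiles))
  recs <- lapply(seq_along(smiles), function(i)
    list(id = ids[[i]], smiles = smiles[[i]]))
  res <- chem_bridge("describe", list(records = recs))
  lapply(seq_along(res), function(i) {
    r <- res[[i]]
    if (identical(r$status, "invalid")) {
      stop("invalid structure: ", smiles[[i]], call. = FALSE)
    }
    if (identical(r$status, "acyclic")) {
      stop("acyclic molecule has no scaffold: ", smiles[[i]],
           " (linear chemicals are removed during curation)", call. = FALSE)
    }
    structure(list(chem_id = ids[[i]],
                   scaffold = r$scaffold,
                   skeleton = r$skeleton,
                   rgroups = sort(vapply(r$rgroups, as.character, "")),
                   scaffold_sig = r$scaffold_sig,
                   skeleton_sig = r$skeleton_sig,
                   n_attachments = as.integer(r$n_attachments)),
              class = "scaffold_decomposition")
  })
}

#' Bemis-Murcko scaffold of a molecule
#'
#' @param smiles Character vector of SMILES; each must contain at least one
#'   ring (acyclic input is an error - such chemicals are removed upstream).
#' @return Character vector of canonical scaffold SMILES.
#' @examples \dontrun{compute_scaffold("Cc1ccccc1")  # "c1ccccc1"}
#' @export
compute_scaffold <- function(smiles) {
  vapply(decompose_rgroups(smiles), function(d) d$scaffold, "")
}

#' Cyclic skeleton of a scaffold
#'
#' Replaces every heavy atom by carbon and every bond by a single bond, then
#' canonicalizes: the result depends only on the scaffold's graph topology
#' (benzene and pyridine scaffolds share the cyclohexane skeleton).
#'
#' @param scaffold_smiles Character vector of scaffold SMILES.
#' @return Character vector of canonical skeleton SMILES.
#' @export
compute_cyclic_skeleton <- function(scaffold_smiles) {
  vapply(decompose_rgroups(scaffold_smiles), function(d) d$skeleton, "")
}

#' Cliff label from the four structural comparisons
#'
#' The pure decision tree behind [classify_pair()], exposed so the label
#' logic can be exercised over all comparison-outcome combinations. With
#' equal scaffolds: equal R-groups and equal topology give `chirality`
#' (nothing but stereochemistry can differ), equal R-groups with different
#' topology give `topology`, different R-groups give `r_group`. With
#' different scaffolds: different skeletons give `unclassified`; equal
#' skeletons give `scaffold_r_group` when the R-groups differ, otherwise
#' `scaffold` (equal topology) or `scaffold_topology`.
#'
#' @param scaffold_equal,skeleton_equal,rgroups_equal,topology_equal Logical
#'   scalars; `skeleton_equal` and `topology_equal` may be `NA` when not
#'   reached by the tree.
#' @return One of the seven labels.
#' @export
classify_from_comparisons <- function(scaffold_equal, skeleton_equal,
                                      rgroups_equal, topology_equal) {
  if (isTRUE(scaffold_equal)) {
    if (isTRUE(rgroups_equal)) {
      if (isTRUE(topology_equal)) "chirality" else "topology"
    } else "r_group"
  } else {
    if (!isTRUE(skeleton_equal)) "unclassified"
    else if (!isTRUE(rgroups_equal)) "scaffold_r_group"
    else if (isTRUE(topology_equal)) "scaffold" else "scaffold_topology"
  }
}

#' Classify one chemical pair into a structural cliff type
#'
#' Compares two [decompose_rgroups()] decompositions: scaffold equality,
#' cyclic-skeleton equality, R-group multiset equality, and R-group topology
#' equality (attachment pattern; compared on the scaffold when the scaffolds
#' match, and on the shared skeleton otherwise).
#'
#' @param dec_i,dec_j `scaffold_decomposition` objects.
#' @return List with `label` (one of `chirality`, `topology`, `r_group`,
#'   `scaffold`, `scaffold_topology`, `scaffold_r_group`, `unclassified`) and
#'   `evidence` (the four comparison outcomes; `NA` where not evaluated).
#' @export
classify_pair <- function(dec_i, dec_j) {
  stopifnot(inherits(dec_i, "scaffold_decomposition"),
            inherits(dec_j, "scaffold_decomposition"))
  scaffold_equal <- identical(dec_i$scaffold, dec_j$scaffold)
  skeleton_equal <- identical(dec_i$skeleton, dec_j$skeleton)
  if (scaffold_equal && !skeleton_equal) {
    stop("internal defect: equal scaffolds with different skeletons for ",
         dec_i$chem_id, " / ", dec_j$chem_id, call. = FALSE)
  }
  rgroups_equal <- identical(dec_i$rgroups, dec_j$rgroups)
  topology_equal <- if (!rgroups_equal) NA else if (scaffold_equal) {
    identical(dec_i$scaffold_sig, dec_j$scaffold_sig)
  } else if (skeleton_equal) {
    identical(dec_i$skeleton_sig, dec_j$skeleton_sig)
  } else NA
  label <- classify_from_comparisons(scaffold_equal, skeleton_equal,
                                     rgroups_equal, topology_equal)
  list(label = label,
       evidence = list(scaffold_equal = scaffold_equal,
                       skeleton_equal = skeleton_equal,
                       rgroups_equal = rgroups_equal,
                       topology_equal = topology_equal))
}

#' Classify a set of activity cliffs
#'
#' Decomposes every chemical once and applies [classify_pair()] to each
#' cliff pair.
#'
#' @param cliffs An [find_activity_cliffs()] result or a data.frame with
#'   `id_i`, `id_j`.
#' @param records Curated records with `chem_id`, `canonical_smiles`.
#' @return data.frame with `id_i`, `id_j`, `label`, `scaffold_i`,
#'   `scaffold_j`, `skeleton_equal`, `rgroups_i`, `rgroups_j`; the label
#'   histogram is attached as attribute `"histogram"`.
#' @export
classify_cliffs <- function(cliffs, records) {
  if (inherits(cliffs, "activity_cliffs")) cliffs <- cliffs$cliffs
  stopifnot(is.data.frame(cliffs), is.data.frame(records))
  empty <- data.frame(id_i = character(), id_j = character(),
                      label = character(), scaffold_i = character(),
                      scaffold_j = character(), skeleton_equal = logical(),
                      rgroups_i = character(), rgroups_j = character(),
                      stringsAsFactors = FALSE)
  if (nrow(cliffs) == 0) {
    attr(empty, "histogram") <- table(factor(character(),
                                             levels = cliff_labels))
    return(empty)
  }
  ids <- unique(c(cliffs$id_i, cliffs$id_j))
  idx <- match(ids, records$chem_id)
  if (anyNA(idx)) {
    stop("cliff chemical(s) absent from records: ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  decs <- decompose_rgroups(records$canonical_smiles[idx], ids)
  names(decs) <- ids
  rows <- lapply(seq_len(nrow(cliffs)), function(k) {
    di <- decs[[cliffs$id_i[k]]]; dj <- decs[[cliffs$id_j[k]]]
    cl <- classify_pair(di, dj)
    data.frame(id_i = cliffs$id_i[k], id_j = cliffs$id_j[k],
               label = cl$label,
               scaffold_i = di$scaffold, scaffold_j = dj$scaffold,
               skeleton_equal = cl$evidence$skeleton_equal,
               rgroups_i = paste(di$rgroups, collapse = "."),
               rgroups_j = paste(dj$rgroups, collapse = "."),
               stringsAsFactors = FALSE)
  })
  out <- rbind_rows(rows)
  attr(out, "histogram") <- table(factor(out$label, levels = cliff_labels))
  out
}
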