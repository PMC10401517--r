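# Mechanism-of-action classification of structurally similar dual-endpoint
# chemical pairs.

moa_labels <- c("strong_moa_cliff", "same_moa", "weak_moa_cliff")

#' Intersect agonist and antagonist datasets
#'
#' Chemicals present (by canonical structure) in both curated datasets, each
#' carrying its agonist and antagonist hit call. Identifiers are taken from
#' the agonist side. A chem_id appearing with two different structures in one
#' dataset is a data error.
#'
#' @param agonists,antagonists Curated records data.frames (see [curate()])
#'   with `chem_id`, `canonical_smiles` and `hit_call`.
#' @return data.frame with `chem_id`, `canonical_smiles`, `agonist_hit`,
#'   `antagonist_hit`.
#' @export
intersect_datasets <- function(agonists, antagonists) {
  stopifnot(is.data.frame(agonists), is.data.frame(antagonists))
  for (d in list(agonists, antagonists)) {
    conflict <- unique(d$chem_id[duplicated(d$chem_id)])
    for (id in conflict) {
      if (length(unique(d$canonical_smiles[d$chem_id == id])) > 1) {
        stop("conflicting structures under chem_id ", id, call. = FALSE)
      }
    }
  }
  shared <- intersect(agonists$canonical_smiles, antagonists$canonical_smiles)
  ai <- match(shared, agonists$canonical_smiles)
  bi <- match(shared, antagonists$canonical_smiles)
  data.frame(chem_id = agonists$chem_id[ai],
             canonical_smiles = shared,
             agonist_hit = agonists$hit_call[ai],
             antagonist_hit = antagonists$hit_call[bi],
             stringsAsFactors = FALSE)
}

#' Drop chemicals inactive in both assays
#'
#' @param records An [intersect_datasets()] result.
#' @return The records with `(inactive, inactive)` annotation tuples removed.
#' @export
filter_active_any <- function(records) {
  stopifnot(is.data.frame(records))
  if (anyNA(records$agonist_hit) || anyNA(records$antagonist_hit)) {
    stop("missing hit call(s) in dual-endpoint records", call. = FALSE)
  }
  keep <- !(records$agonist_hit == "inactive" &
              records$antagonist_hit == "inactive")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Structurally similar dual-endpoint pairs
#'
#' All unordered pairs with ECFP4 Tanimoto similarity strictly above
#' `sim_threshold` (the same threshold, and operator, as the SAS map's
#' similarity axis).
#'
#' @param records A filtered [intersect_datasets()] result.
#' @param sim_threshold Similarity threshold; default 0.35.
#' @param n_bits Fingerprint length; default 2048.
#' @return data.frame with `id_i`, `id_j`, `tanimoto`.
#' @export
similar_pairs <- function(records, sim_threshold = 0.35, n_bits = 2048) {
  stopifnot(is.data.frame(records))
  empty <- data.frame(id_i = character(), id_j = character(),
                      tanimoto = numeric(), stringsAsFactors = FALSE)
  if (nrow(records) < 2) return(empty)
  fps <- compute_ecfp4(records$canonical_smiles, n_bits)
  s <- pairwise_tanimoto_matrix(fps)
  idx <- which(upper.tri(s) & s > sim_threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  id_a <- records$chem_id[idx[, 1]]
  id_b <- records$chem_id[idx[, 2]]
  swap <- id_a > id_b
  out <- data.frame(id_i = ifelse(swap, id_b, id_a),
                    id_j = ifelse(swap, id_a, id_b),
                    tanimoto = s[idx], stringsAsFactors = FALSE)
  out <- out[order(out$id_i, out$id_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify one dual-endpoint pair by its annotation tuples
#'
#' `strong_moa_cliff` when the two (agonist, antagonist) hit tuples are
#' element-wise opposite; `same_moa` when they are equal; `weak_moa_cliff`
#' otherwise. Vectorized.
#'
#' @param agonist_i,antagonist_i,agonist_j,antagonist_j Hit calls
#'   (`"active"`/`"inactive"`).
#' @return Character vector of labels.
#' @examples
#' classify_moa_pair("inactive", "active", "active", "inactive")  # strong
#' @export
classify_moa_pair <- function(agonist_i, antagonist_i,
                              agonist_j, antagonist_j) {
  ok <- c("active", "inactive")
  stopifnot(all(agonist_i %in% ok), all(antagonist_i %in% ok),
            all(agonist_j %in% ok), all(antagonist_j %in% ok))
  same <- agonist_i == agonist_j & antagonist_i == antagonist_j
  opposite <- agonist_i != agonist_j & antagonist_i != antagonist_j
  ifelse(same, "same_moa",
         ifelse(opposite, "strong_moa_cliff", "weak_moa_cliff"))
}

#' Classify all similar dual-endpoint pairs
#'
#' @param pairs A [similar_pairs()] result.
#' @param records The filtered dual-endpoint records the pairs were drawn
#'   from.
#' @return data.frame with `id_i`, `id_j`, `tanimoto`, the four hit calls and
#'   `label`; histogram attached as attribute `"histogram"`.
#' @export
classify_moa_pairs <- function(pairs, records) {
  stopifnot(is.data.frame(pairs), is.data.frame(records))
  i <- match(pairs$id_i, records$chem_id)
  j <- match(pairs$id_j, records$chem_id)
  if (anyNA(i) || anyNA(j)) {
    stop("pair chemical(s) absent from records", call. = FALSE)
  }
  out <- pairs
  out$agonist_i <- records$agonist_hit[i]
  out$antagonist_i <- records$antagonist_hit[i]
  out$agonist_j <- records$agonist_hit[j]
  out$antagonist_j <- records$antagonist_hit[j]
  out$label <- if (nrow(out))
    classify_moa_pair(out$agonist_i, out$antagonist_i,
                      out$agonist_j, out$antagonist_j) else character()
  attr(out, "histogram") <- table(factor(out$label, levels = moa_labels))
  out
}
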