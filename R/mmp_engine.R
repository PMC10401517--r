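# Matched molecular pairs: fragmentation, indexing, size restriction,
# MMP-cliff calling.

#' @import data.table
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  "constant", "variable", "parent_id", "id_i", "id_j", "frag_i", "frag_j",
  "frag_i_heavy", "frag_j_heavy", "constant_heavy", "n_cuts", "heavy_diff",
  "heavy_total", ".SD", "i.parent_id", "i.variable", "i.variable_heavy"
))

#' Fragment molecules for MMP indexing
#'
#' Enumerates all fragmentations of each molecule obtained by cutting 1 to
#' `max_cuts` acyclic single bonds (the standard carbon-anchored matched-pair
#' cut rule; ring bonds are never cut). For a k-cut fragmentation the
#' "variable" part is the single fragment carrying all k attachment points and
#' the "constant" part is the remaining fragments. Single-cut fragmentations
#' are emitted in both orientations. When `hydrogen = TRUE`, single-cut
#' hydrogen substitutions are added (variable part a labelled hydrogen, zero
#' heavy atoms). Attachment points are serialized as numbered wildcards with a
#' canonical label permutation so that identical constant parts hash equal.
#'
#' @param records Curated records data.frame (`chem_id`, `canonical_smiles`),
#'   or a character vector of SMILES (ids default to the SMILES).
#' @param max_cuts Maximum simultaneous bond cuts (1-3); default 3.
#' @param hydrogen Include hydrogen-substitution fragmentations; default TRUE.
#' @return data.frame with `parent_id`, `constant`, `variable`, `n_cuts`,
#'   `constant_heavy`, `variable_heavy`.
#' @export
fragment_molecules <- function(records, max_cuts = 3, hydrogen = TRUE) {
  if (is.character(records)) {
    records <- data.frame(chem_id = records, canonical_smiles = records,
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(records), max_cuts >= 1, max_cuts <= 3)
  recs <- lapply(seq_len(nrow(records)), function(i)
    list(id = records$chem_id[[i]], smiles = records$canonical_smiles[[i]]))
  res <- chem_bridge("fragment", list(records = recs, max_cuts = max_cuts,
                                      hydrogen = hydrogen))
  bad <- vapply(res, function(r) !identical(r$status, "ok"), TRUE)
  if (any(bad)) {
    stop("invalid structure(s) in MMP fragmentation: ",
         paste(vapply(res[bad], function(r) r$id, ""), collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(res, function(r) {
    if (length(r$fragmentations) == 0) return(NULL)
    data.frame(
      parent_id = r$id,
      constant = vapply(r$fragmentations, function(f) f$constant, ""),
      variable = vapply(r$fragmentations, function(f) f$variable, ""),
      n_cuts = vapply(r$fragmentations, function(f) as.integer(f$n_cuts), 1L),
      constant_heavy = vapply(r$fragmentations,
                              function(f) as.integer(f$constant_heavy), 1L),
      variable_heavy = vapply(r$fragmentations,
                              function(f) as.integer(f$variable_heavy), 1L),
      stringsAsFactors = FALSE
    )
  })
  out <- rbind_rows(rows)
  if (is.null(out)) {
    out <- data.frame(parent_id = character(), constant = character(),
                      variable = character(), n_cuts = integer(),
                      constant_heavy = integer(), variable_heavy = integer(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Index matched molecular pairs from fragmentations
#'
#' Groups fragmentations by their canonical constant part; every
#' cross-chemical pair within a group whose variable parts differ yields one
#' MMP transformation. Unordered pairs are deduplicated by orienting each
#' record so that `id_i < id_j`; the output is invariant to input record
#' order.
#'
#' @param fragmentations A [fragment_molecules()] result.
#' @return data.frame with `id_i`, `id_j`, `constant`, `frag_i`, `frag_j`,
#'   `frag_i_heavy`, `frag_j_heavy`, `constant_heavy`, `n_cuts` - one row per
#'   (pair, transformation).
#' @export
index_mmps <- function(fragmentations) {
  stopifnot(is.data.frame(fragmentations))
  empty <- data.frame(id_i = character(), id_j = character(),
                      constant = character(), frag_i = character(),
                      frag_j = character(), frag_i_heavy = integer(),
                      frag_j_heavy = integer(), constant_heavy = integer(),
                      n_cuts = integer(), stringsAsFactors = FALSE)
  if (nrow(fragmentations) == 0) return(empty)
  dt <- data.table::as.data.table(fragmentations)
  joined <- dt[dt, on = "constant", allow.cartesian = TRUE, nomatch = NULL]
  joined <- joined[parent_id < i.parent_id & variable != i.variable]
  if (nrow(joined) == 0) return(empty)
  out <- joined[, list(
    id_i = parent_id, id_j = i.parent_id, constant = constant,
    frag_i = variable, frag_j = i.variable,
    frag_i_heavy = variable_heavy, frag_j_heavy = i.variable_heavy,
    constant_heavy = constant_heavy, n_cuts = n_cuts)]
  out <- unique(out)
  data.table::setorder(out, id_i, id_j, constant, frag_i, frag_j)
  as.data.frame(out)
}

#' Apply the four MMP size-restriction criteria
#'
#' Filters indexed transformations by: (i) the heavy-atom difference between
#' exchanged fragments is at most `max_heavy_diff`; (ii) the constant part
#' has at least `constant_factor` times the heavy atoms of each exchanged
#' fragment; (iii) each exchanged fragment has at most `max_frag_heavy` heavy
#' atoms. Criterion (iv) then selects, for each unordered chemical pair with
#' several surviving transformations, the one with the least heavy-atom
#' difference between the exchanged fragments (ties: smallest total fragment
#' size, then lexicographically smallest transformation string). Hydrogen
#' fragments count zero heavy atoms, so criterion (ii) is vacuous for them.
#'
#' @param mmps An [index_mmps()] result.
#' @param max_heavy_diff Criterion (i) bound; default 8.
#' @param max_frag_heavy Criterion (iii) bound; default 13.
#' @param constant_factor Criterion (ii) multiplier; default 2.
#' @return data.frame like the input but with at most one row per unordered
#'   chemical pair.
#' @export
apply_size_restrictions <- function(mmps, max_heavy_diff = 8,
                                    max_frag_heavy = 13,
                                    constant_factor = 2) {
  stopifnot(is.data.frame(mmps))
  if (nrow(mmps) == 0) return(mmps)
  dt <- data.table::as.data.table(mmps)
  dt <- dt[abs(frag_i_heavy - frag_j_heavy) <= max_heavy_diff &
             pmax(frag_i_heavy, frag_j_heavy) <= max_frag_heavy &
             constant_heavy >= constant_factor * frag_i_heavy &
             constant_heavy >= constant_factor * frag_j_heavy]
  if (nrow(dt) == 0) return(as.data.frame(dt))
  dt[, heavy_diff := abs(frag_i_heavy - frag_j_heavy)]
  dt[, heavy_total := frag_i_heavy + frag_j_heavy]
  data.table::setorder(dt, id_i, id_j, heavy_diff, heavy_total, constant,
                       frag_i, frag_j)
  sel <- dt[, .SD[1], by = c("id_i", "id_j")]
  sel[, c("heavy_diff", "heavy_total") := NULL]
  as.data.frame(sel)
}

#' Call MMP-cliffs among size-restricted MMPs
#'
#' Joins each size-restricted pair with the chemicals' pAC50 values and flags
#' pairs with an activity difference of at least `act_threshold` log units as
#' MMP-cliffs.
#'
#' @param restricted An [apply_size_restrictions()] result.
#' @param records Curated records with `chem_id` and `pac50` (the pAC50
#'   lookup).
#' @param act_threshold Cliff threshold in log units; default 2.
#' @return Object of class `mmp_cliffs`: list with `mmps` (all restricted
#'   pairs with `activity_diff` and `is_cliff` columns) and `cliffs` (the
#'   flagged subset).
#' @export
find_mmp_cliffs <- function(restricted, records, act_threshold = 2.0) {
  stopifnot(is.data.frame(restricted), is.data.frame(records))
  pac50 <- stats::setNames(records$pac50, records$chem_id)
  if (nrow(restricted)) {
    missing <- setdiff(unique(c(restricted$id_i, restricted$id_j)),
                       names(pac50)[!is.na(pac50)])
    if (length(missing)) {
      stop("no pAC50 available for chemical(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  out <- restricted
  out$activity_diff <- if (nrow(out))
    activity_difference(pac50[out$id_i], pac50[out$id_j]) else numeric()
  out$is_cliff <- out$activity_diff >= act_threshold
  rownames(out) <- NULL
  structure(list(mmps = out,
                 cliffs = out[out$is_cliff, , drop = FALSE],
                 act_threshold = act_threshold),
            class = "mmp_cliffs")
}

#' @export
print.mmp_cliffs <- function(x, ...) {
  cat("Size-restricted MMPs:", nrow(x$mmps), "pairs;",
      nrow(x$cliffs), "MMP-cliffs (activity difference >=",
      x$act_threshold, ")\n")
  invisible(x)
}

#' Compare MMP-cliffs with SAS-map activity cliffs
#'
#' Reports the overlap between the two cliff callers on the same dataset.
#' The subset relation (every MMP-cliff also a SAS cliff) is reported, not
#' assumed.
#'
#' @param mmp_cliffs A [find_mmp_cliffs()] result (or its `cliffs`
#'   data.frame).
#' @param sas_cliffs A [find_activity_cliffs()] result (or its `cliffs`
#'   data.frame).
#' @return List with the two cardinalities, the intersection size, each
#'   side's exclusive pairs, and `mmp_subset_of_sas`.
#' @export
compare_with_sas <- function(mmp_cliffs, sas_cliffs) {
  if (inherits(mmp_cliffs, "mmp_cliffs")) mmp_cliffs <- mmp_cliffs$cliffs
  if (inherits(sas_cliffs, "activity_cliffs")) sas_cliffs <- sas_cliffs$cliffs
  key <- function(df) if (nrow(df) == 0) character() else
    paste(pmin(df$id_i, df$id_j), pmax(df$id_i, df$id_j), sep = "|")
  mk <- unique(key(mmp_cliffs))
  sk <- unique(key(sas_cliffs))
  list(n_mmp_cliffs = length(mk),
       n_sas_cliffs = length(sk),
       n_intersection = length(intersect(mk, sk)),
       mmp_only = setdiff(mk, sk),
       sas_only = setdiff(sk, mk),
       mmp_subset_of_sas = length(setdiff(mk, sk)) == 0)
}
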