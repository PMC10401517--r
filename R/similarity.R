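# ECFP4 fingerprints and Tanimoto similarity.

#' Compute folded ECFP4 fingerprints
#'
#' Extended-connectivity fingerprints of diameter 4 (Morgan radius 2), folded
#' to `n_bits` bits. Chirality is not encoded: the whole workflow operates on
#' stereo-stripped structure keys. The fingerprint is deterministic for a
#' given structure and length.
#'
#' @param smiles Character vector of (canonical) SMILES.
#' @param n_bits Folded length; community default 2048.
#' @return A list of sorted 0-based on-bit integer vectors, of class
#'   `ecfp_list`, with an `n_bits` attribute.
#' @export
compute_ecfp4 <- function(smiles, n_bits = 2048) {
  stopifnot(is.character(smiles), length(smiles) >= 1, n_bits >= 8)
  res <- chem_bridge("fingerprint",
                     list(smiles = I(smiles), n_bits = n_bits))
  bits <- lapply(seq_along(res$bits), function(i) {
    b <- res$bits[[i]]
    if (is.null(b)) {
      stop("invalid structure for fingerprinting: ", smiles[[i]],
           call. = FALSE)
    }
    sort(vapply(b, as.integer, 1L))
  })
  structure(bits, class = "ecfp_list", n_bits = as.integer(n_bits))
}

#' Tanimoto coefficient between two fingerprints
#'
#' `|A intersect B| / |A union B|` over on-bit sets; 1 for identical
#' fingerprints, 0 for disjoint ones.
#'
#' @param fp_a,fp_b Integer vectors of on-bit positions (elements of an
#'   [compute_ecfp4()] result).
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  na <- attr(fp_a, "n_bits"); nb <- attr(fp_b, "n_bits")
  if (!is.null(na) && !is.null(nb) && na != nb) {
    stop("fingerprints have different lengths (", na, " vs ", nb, ")",
         call. = FALSE)
  }
  u <- length(union(fp_a, fp_b))
  if (u == 0) return(1)
  length(intersect(fp_a, fp_b)) / u
}

# Dense 0/1 matrix from a fingerprint list; rows = molecules.
fp_matrix <- function(fps, n_bits = attr(fps, "n_bits")) {
  m <- matrix(0, nrow = length(fps), ncol = n_bits)
  for (i in seq_along(fps)) m[i, fps[[i]] + 1L] <- 1
  m
}

# All pairwise Tanimoto similarities via bit-count algebra:
# |A & B| from the cross-product of the 0/1 matrix, |A | B| = |A|+|B|-|A & B|.
pairwise_tanimoto_matrix <- function(fps) {
  m <- fp_matrix(fps)
  inter <- tcrossprod(m)
  pop <- diag(inter)
  uni <- outer(pop, pop, "+") - inter
  s <- inter / uni
  s[uni == 0] <- 1
  s
}

#' Pairwise similarity / activity-difference table
#'
#' Computes all `n(n-1)/2` unordered chemical pairs with their ECFP4 Tanimoto
#' similarity and absolute pAC50 difference; the substrate for the SAS map.
#' Within each pair `id_i < id_j` lexicographically.
#'
#' @param records Curated records data.frame with `chem_id`,
#'   `canonical_smiles` and `pac50` columns (see [curate()]).
#' @param n_bits Fingerprint length.
#' @param fps Optional precomputed [compute_ecfp4()] result for
#'   `records$canonical_smiles`.
#' @return data.frame with columns `id_i`, `id_j`, `tanimoto`,
#'   `activity_diff`.
#' @export
pairwise_table <- function(records, n_bits = 2048, fps = NULL) {
  stopifnot(is.data.frame(records), nrow(records) >= 2)
  if (is.null(fps)) fps <- compute_ecfp4(records$canonical_smiles, n_bits)
  s <- pairwise_tanimoto_matrix(fps)
  idx <- which(upper.tri(s), arr.ind = TRUE)
  id_a <- records$chem_id[idx[, 1]]
  id_b <- records$chem_id[idx[, 2]]
  swap <- id_a > id_b
  out <- data.frame(
    id_i = ifelse(swap, id_b, id_a),
    id_j = ifelse(swap, id_a, id_b),
    tanimoto = s[idx],
    activity_diff = activity_difference(records$pac50[idx[, 1]],
                                        records$pac50[idx[, 2]]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$id_i, out$id_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Data-driven similarity-threshold diagnostic
#'
#' Returns `median(tanimoto) + 3 * sd(tanimoto)` over all pairs. This mixes a
#' robust location estimate with the sample standard deviation about the
#' mean, and is reported as a diagnostic only: the pipeline default threshold
#' stays at 0.35 unless explicitly overridden.
#'
#' @param pairs A [pairwise_table()] result.
#' @return A single numeric value.
#' @export
suggest_similarity_threshold <- function(pairs) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 2)
  s <- stats::sd(pairs$tanimoto)
  if (is.na(s)) s <- 0
  stats::median(pairs$tanimoto) + 3 * s
}
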