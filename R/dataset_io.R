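# Reading, standardizing and curating chemical activity tables.

#' Default raw-table column mapping
#'
#' Maps the package's canonical field names to the column names expected in an
#' input table. Override individual entries via the `column_map` argument of
#' [parse_activity_table()].
#' @return Named character vector.
#' @export
default_column_map <- function() {
  c(chem_id = "chem_id", name = "name", smiles = "smiles",
    modl_ga = "modl_ga", hit_call = "hit_c", endpoint = "endpoint")
}

normalize_hit_call <- function(x) {
  x <- trimws(tolower(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("1", "active", "a", "true")] <- "active"
  out[x %in% c("0", "inactive", "i", "false")] <- "inactive"
  out
}

#' Read a raw chemical activity table
#'
#' Parses a CSV/TSV file into raw records with the fields `chem_id`, `name`,
#' `smiles`, `modl_ga`, `hit_call` and `endpoint`. Unmapped columns are kept
#' as pass-through metadata. Rows whose activity cell does not parse as a
#' number get `modl_ga = NA`; row order is preserved.
#'
#' @param path Path to the input file.
#' @param format `"csv"` or `"tsv"`.
#' @param column_map Named character vector mapping canonical field names to
#'   file column names; see [default_column_map()]. `name`, `hit_call` and
#'   `endpoint` entries may be absent from the file; `chem_id`, `smiles` and
#'   `modl_ga` must be present.
#' @param endpoint Optional endpoint label (`"agonist"`/`"antagonist"`) used
#'   when the file has no endpoint column.
#' @return A data.frame of raw records.
#' @export
parse_activity_table <- function(path, format = c("csv", "tsv"),
                                 column_map = default_column_map(),
                                 endpoint = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  cmap <- default_column_map()
  cmap[names(column_map)] <- column_map
  sep <- if (format == "csv") "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  required <- c("chem_id", "smiles", "modl_ga")
  for (field in required) {
    if (!cmap[[field]] %in% names(tab)) {
      stop("input table lacks mapped column '", cmap[[field]], "' (field ",
           field, ")", call. = FALSE)
    }
  }
  out <- data.frame(
    chem_id = as.character(tab[[cmap[["chem_id"]]]]),
    name = if (cmap[["name"]] %in% names(tab))
      as.character(tab[[cmap[["name"]]]]) else NA_character_,
    smiles = as.character(tab[[cmap[["smiles"]]]]),
    modl_ga = suppressWarnings(as.numeric(tab[[cmap[["modl_ga"]]]])),
    hit_call = if (cmap[["hit_call"]] %in% names(tab))
      normalize_hit_call(tab[[cmap[["hit_call"]]]]) else NA_character_,
    endpoint = if (cmap[["endpoint"]] %in% names(tab))
      tolower(as.character(tab[[cmap[["endpoint"]]]]))
    else if (!is.null(endpoint)) endpoint else NA_character_,
    stringsAsFactors = FALSE
  )
  if (any(!out$endpoint %in% c("agonist", "antagonist", NA_character_))) {
    stop("endpoint values must be 'agonist' or 'antagonist'", call. = FALSE)
  }
  if (any(!nzchar(out$chem_id))) stop("empty chem_id in input", call. = FALSE)
  meta <- setdiff(names(tab), unname(cmap))
  for (m in meta) out[[m]] <- tab[[m]]
  out
}

#' Standardize a batch of SMILES strings
#'
#' Strips recognized inorganic counter-ion/solvent fragments, collapses
#' duplicated identical fragments, neutralizes the surviving fragment and
#' canonicalizes it (stereochemistry-stripped canonical SMILES is the
#' package-wide structure key). A structure is rejected as `"mixture"` when
#' two or more distinct non-salt fragments remain, and as `"invalid"` when it
#' does not parse or nothing organic survives stripping.
#'
#' @param smiles Character vector of SMILES strings.
#' @return data.frame with columns `smiles`, `status`
#'   (`"ok"`/`"invalid"`/`"mixture"`), `canonical_smiles`, `smiles_stereo`,
#'   `heavy_atoms`, `n_rings`.
#' @export
standardize_structures <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) {
    return(data.frame(smiles = character(), status = character(),
                      canonical_smiles = character(),
                      smiles_stereo = character(),
                      heavy_atoms = integer(), n_rings = integer(),
                      stringsAsFactors = FALSE))
  }
  recs <- lapply(seq_along(smiles), function(i)
    list(id = i, smiles = smiles[[i]]))
  res <- chem_bridge("standardize", list(records = recs))
  pick <- function(r, f, default) if (is.null(r[[f]])) default else r[[f]]
  data.frame(
    smiles = smiles,
    status = vapply(res, pick, "", f = "status", default = NA_character_),
    canonical_smiles = vapply(res, pick, "", f = "canonical_smiles",
                              default = NA_character_),
    smiles_stereo = vapply(res, pick, "", f = "smiles_stereo",
                           default = NA_character_),
    heavy_atoms = vapply(res, function(r)
      as.integer(pick(r, "heavy_atoms", NA_integer_)), 1L),
    n_rings = vapply(res, function(r)
      as.integer(pick(r, "n_rings", NA_integer_)), 1L),
    stringsAsFactors = FALSE
  )
}

#' Standardize a single structure
#'
#' @param smiles One SMILES string.
#' @return A list with `status` and, when accepted, `canonical_smiles`.
#' @examples \dontrun{standardize_structure("CC(=O)O.[Na+]")}
#' @export
standardize_structure <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1, nzchar(smiles))
  row <- standardize_structures(smiles)
  if (row$status == "ok") {
    list(status = "ok", canonical_smiles = row$canonical_smiles,
         heavy_atoms = row$heavy_atoms, n_rings = row$n_rings)
  } else {
    list(status = "rejected", reason = row$status)
  }
}

#' Remove duplicated structures within each endpoint
#'
#' At most one record per canonical structure per endpoint is kept (the first
#' in input order). Inputs differing only in stereochemistry share a canonical
#' key and are therefore duplicates.
#'
#' @param records data.frame of standardized records with `canonical_smiles`
#'   and `endpoint` columns.
#' @return The deduplicated data.frame, with a `"removed"` attribute logging
#'   `(dropped_id, kept_id)` pairs.
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0) {
    attr(records, "removed") <- data.frame(dropped_id = character(),
                                           kept_id = character())
    return(records)
  }
  key <- paste(records$endpoint, records$canonical_smiles, sep = "\r")
  first <- !duplicated(key)
  kept_for <- records$chem_id[match(key, key)]  # id of first holder of key
  removed <- data.frame(dropped_id = records$chem_id[!first],
                        kept_id = kept_for[!first],
                        stringsAsFactors = FALSE)
  out <- records[first, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Remove linear (ring-free) chemicals
#'
#' A chemical whose Bemis-Murcko scaffold is empty contains no ring and is
#' removed; ring count zero is an equivalent and cheaper test.
#'
#' @param records data.frame of standardized records; if an `n_rings` column
#'   is absent it is recomputed from `canonical_smiles`.
#' @return Filtered data.frame with a `"removed"` attribute of dropped ids.
#' @export
remove_linear <- function(records) {
  if (nrow(records) == 0) {
    attr(records, "removed") <- character()
    return(records)
  }
  n_rings <- records$n_rings
  if (is.null(n_rings)) {
    n_rings <- standardize_structures(records$canonical_smiles)$n_rings
  }
  keep <- !is.na(n_rings) & n_rings >= 1
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- records$chem_id[!keep]
  out
}

#' Curate a raw activity table into a chemical dataset
#'
#' Applies, in order: drop records without a reported activity (`modl_ga`
#' missing); standardize structures (dropping invalid structures and
#' mixtures); compute `pac50 = 6 - modl_ga`; deduplicate per endpoint on the
#' canonical structure; remove linear (ring-free) chemicals. Counts dropped at
#' each step are reported.
#'
#' @param raw data.frame of raw records as returned by
#'   [parse_activity_table()].
#' @return An object of class `sc_curation`: a list with `records` (curated
#'   data.frame with `chem_id`, `name`, `canonical_smiles`, `smiles_stereo`,
#'   `modl_ga`, `pac50`, `hit_call`, `endpoint`, `heavy_atoms`, `n_rings`),
#'   `report` (named integer vector of per-step drop counts) and `log`
#'   (data.frame naming each dropped record and the step that dropped it).
#' @export
curate <- function(raw) {
  stopifnot(is.data.frame(raw))
  if (is.null(raw$hit_call) && !is.null(raw$hit_c)) {
    raw$hit_call <- normalize_hit_call(raw$hit_c)
  }
  n_input <- nrow(raw)
  log <- data.frame(chem_id = character(), step = character(),
                    detail = character(), stringsAsFactors = FALSE)
  note <- function(ids, step, detail = "") {
    if (length(ids)) rbind(log, data.frame(chem_id = ids, step = step,
                                           detail = detail,
                                           stringsAsFactors = FALSE))
    else log
  }

  has_act <- !is.na(raw$modl_ga)
  log <- note(raw$chem_id[!has_act], "missing_activity")
  cur <- raw[has_act, , drop = FALSE]

  std <- if (nrow(cur)) standardize_structures(cur$smiles) else
    standardize_structures(character())
  n_invalid <- sum(std$status == "invalid")
  n_mixture <- sum(std$status == "mixture")
  log <- note(cur$chem_id[std$status == "invalid"], "invalid")
  log <- note(cur$chem_id[std$status == "mixture"], "mixture")
  ok <- std$status == "ok"
  cur <- cur[ok, , drop = FALSE]
  std <- std[ok, , drop = FALSE]

  records <- data.frame(
    chem_id = cur$chem_id,
    name = if (is.null(cur$name)) NA_character_ else cur$name,
    canonical_smiles = std$canonical_smiles,
    smiles_stereo = std$smiles_stereo,
    modl_ga = cur$modl_ga,
    pac50 = if (nrow(cur)) modl_ga_to_pac50(cur$modl_ga) else numeric(),
    hit_call = if (is.null(cur$hit_call)) NA_character_ else cur$hit_call,
    endpoint = if (is.null(cur$endpoint)) NA_character_ else cur$endpoint,
    heavy_atoms = std$heavy_atoms,
    n_rings = std$n_rings,
    stringsAsFactors = FALSE
  )

  records <- deduplicate(records)
  dup <- attr(records, "removed")
  log <- note(dup$dropped_id, "duplicate",
              if (nrow(dup)) paste("kept", dup$kept_id) else "")

  records <- remove_linear(records)
  lin <- attr(records, "removed")
  log <- note(lin, "linear")
  attr(records, "removed") <- NULL
  rownames(records) <- NULL

  report <- c(n_input = n_input,
              missing_activity = sum(!has_act),
              invalid = n_invalid,
              mixture = n_mixture,
              duplicate = nrow(dup),
              linear = length(lin),
              n_curated = nrow(records))
  structure(list(records = records, report = report, log = log),
            class = "sc_curation")
}

#' @export
print.sc_curation <- function(x, ...) {
  r <- x$report
  cat("Curated chemical dataset:", r[["n_curated"]], "of", r[["n_input"]],
      "records retained\n")
  cat("  dropped: missing activity", r[["missing_activity"]],
      "| invalid", r[["invalid"]], "| mixture", r[["mixture"]],
      "| duplicate", r[["duplicate"]], "| linear", r[["linear"]], "\n")
  invisible(x)
}

#' Write a curated dataset and its curation report
#'
#' @param curation An `sc_curation` object from [curate()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the paths written.
#' @export
write_curated <- function(curation, dir, prefix = "curated") {
  stopifnot(inherits(curation, "sc_curation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data_path <- file.path(dir, paste0(prefix, ".csv"))
  report_path <- file.path(dir, paste0(prefix, "_report.json"))
  utils::write.csv(curation$records, data_path, row.names = FALSE)
  jsonlite::write_json(list(report = as.list(curation$report),
                            log = curation$log),
                       report_path, auto_unbox = TRUE, digits = NA)
  invisible(c(data = data_path, report = report_path))
}
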