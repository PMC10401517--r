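# End-to-end orchestration: curate -> pairs -> SAS -> MMP -> classify -> MOA.

#' Pipeline run configuration
#'
#' A single object holding every tunable the stages read, so thresholds can
#' never diverge between stages. Defaults are the workflow's standard values:
#' similarity 0.35, activity difference 2 log units, ACG minimum 5 cliff
#' pairs, 2048-bit ECFP4, up to 3 cuts for MMP fragmentation.
#'
#' @param agonist_input,antagonist_input Paths to raw activity tables (either
#'   may be `NULL`).
#' @param format `"csv"` or `"tsv"`.
#' @param column_map Column mapping for [parse_activity_table()].
#' @param out_dir Output directory for artifacts.
#' @param sim_threshold,act_threshold SAS thresholds.
#' @param acg_min_pairs ACG cliff-pair minimum.
#' @param n_bits Fingerprint length.
#' @param max_cuts MMP fragmentation cut maximum.
#' @param render_maps Write SAS-map images; default TRUE.
#' @return A `run_config` object.
#' @export
run_config <- function(agonist_input = NULL, antagonist_input = NULL,
                       format = "csv", column_map = default_column_map(),
                       out_dir = tempfile("sascliffs_run_"),
                       sim_threshold = 0.35, act_threshold = 2.0,
                       acg_min_pairs = 5, n_bits = 2048, max_cuts = 3,
                       render_maps = TRUE) {
  stopifnot(sim_threshold > 0, act_threshold > 0, acg_min_pairs >= 1,
            n_bits >= 8, max_cuts >= 1, max_cuts <= 3)
  structure(list(agonist_input = agonist_input,
                 antagonist_input = antagonist_input,
                 format = format, column_map = column_map,
                 out_dir = out_dir,
                 sim_threshold = sim_threshold,
                 act_threshold = act_threshold,
                 acg_min_pairs = acg_min_pairs,
                 n_bits = n_bits, max_cuts = max_cuts,
                 render_maps = render_maps),
            class = "run_config")
}

run_endpoint_stages <- function(records, config, tag, out_dir) {
  thresholds <- sas_thresholds(config$sim_threshold, config$act_threshold)
  pairs <- pairwise_table(records, n_bits = config$n_bits)
  utils::write.csv(pairs, file.path(out_dir, paste0(tag, "_pairs.csv")),
                   row.names = FALSE)
  cliffs <- find_activity_cliffs(pairs, thresholds)
  utils::write.csv(cliffs$cliffs,
                   file.path(out_dir, paste0(tag, "_cliffs.csv")),
                   row.names = FALSE)
  acgs <- find_acgs(cliffs, min_pairs = config$acg_min_pairs)
  utils::write.csv(acgs, file.path(out_dir, paste0(tag, "_acgs.csv")),
                   row.names = FALSE)
  if (isTRUE(config$render_maps)) {
    render_sas_map(pairs, thresholds,
                   file.path(out_dir, paste0(tag, "_sas_map.png")))
  }
  frags <- fragment_molecules(records, max_cuts = config$max_cuts)
  mmps <- index_mmps(frags)
  restricted <- apply_size_restrictions(mmps)
  mmp_res <- find_mmp_cliffs(restricted, records,
                             act_threshold = config$act_threshold)
  utils::write.csv(mmp_res$mmps,
                   file.path(out_dir, paste0(tag, "_mmps.csv")),
                   row.names = FALSE)
  overlap <- compare_with_sas(mmp_res, cliffs)
  classified <- classify_cliffs(cliffs, records)
  utils::write.csv(classified,
                   file.path(out_dir, paste0(tag, "_cliffs_classified.csv")),
                   row.names = FALSE)
  histogram <- attr(classified, "histogram")
  list(
    counts = list(
      n_curated = nrow(records),
      n_pairs = nrow(pairs),
      region_counts = as.list(setNames(as.integer(cliffs$region_counts),
                                       names(cliffs$region_counts))),
      n_cliffs = nrow(cliffs$cliffs),
      n_unique_cliff_chemicals = cliffs$n_unique_chemicals,
      n_acgs = nrow(acgs),
      n_mmps_indexed = nrow(mmps),
      n_mmps_restricted = nrow(restricted),
      n_mmp_cliffs = nrow(mmp_res$cliffs),
      mmp_cliffs_subset_of_sas = overlap$mmp_subset_of_sas,
      classification_histogram = as.list(setNames(as.integer(histogram),
                                                  names(histogram)))
    ),
    cliffs = cliffs, mmp = mmp_res, pairs = pairs
  )
}

#' Run the full structure-activity landscape pipeline
#'
#' Executes, per endpoint: curation, pairwise similarity/activity table, SAS
#' map with activity cliffs and ACGs, MMP fragmentation/indexing with size
#' restrictions and MMP-cliffs, and cliff classification; when both endpoints
#' are supplied, the dual-endpoint MOA classification is run on the curated
#' datasets. All intermediate artifacts are written under `config$out_dir`
#' and a manifest of per-stage counts is returned and written as JSON.
#'
#' @param config A [run_config()] object, or arguments forwarded to it.
#' @param agonists,antagonists Optional pre-parsed raw data.frames (take
#'   precedence over the file paths in `config`).
#' @return The manifest, invisibly also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config = run_config(), agonists = NULL,
                         antagonists = NULL) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config[setdiff(names(config),
                                           c("column_map"))])
  datasets <- list()
  for (ep in c("agonist", "antagonist")) {
    raw <- if (ep == "agonist") agonists else antagonists
    path <- config[[paste0(ep, "_input")]]
    if (is.null(raw) && !is.null(path)) {
      raw <- parse_activity_table(path, format = config$format,
                                  column_map = config$column_map,
                                  endpoint = ep)
    }
    if (is.null(raw)) next
    cur <- curate(raw)
    write_curated(cur, out_dir, prefix = paste0("curated_", ep))
    stage <- run_endpoint_stages(cur$records, config, ep, out_dir)
    manifest[[ep]] <- c(list(curation_report = as.list(cur$report)),
                        stage$counts)
    datasets[[ep]] <- cur$records
  }
  if (length(datasets) == 2) {
    dual <- intersect_datasets(datasets$agonist, datasets$antagonist)
    n_common <- nrow(dual)
    dual <- filter_active_any(dual)
    pairs <- similar_pairs(dual, sim_threshold = config$sim_threshold,
                           n_bits = config$n_bits)
    moa <- classify_moa_pairs(pairs, dual)
    utils::write.csv(moa, file.path(out_dir, "moa_pairs.csv"),
                     row.names = FALSE)
    hist <- attr(moa, "histogram")
    manifest$moa <- list(
      n_common = n_common,
      n_active_any = nrow(dual),
      n_similar_pairs = nrow(pairs),
      histogram = as.list(setNames(as.integer(hist), names(hist)))
    )
  }
  if (length(datasets) == 0) {
    stop("no input dataset supplied to run_pipeline()", call. = FALSE)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
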