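# SAS-map regions, activity cliffs and activity cliff generators.

#' SAS-map thresholds
#'
#' A pair is "similar" when its Tanimoto coefficient is strictly greater than
#' `sim_threshold`, and "activity-different" when its absolute pAC50
#' difference is at least `act_threshold` (2 log units = 100-fold). The two
#' boundary operators deliberately differ (strict `>` for similarity,
#' `>=` for activity difference).
#'
#' @param sim_threshold Similarity threshold in (0, 1); default 0.35.
#' @param act_threshold Activity-difference threshold in log units; default 2.
#' @return An object of class `sas_thresholds`.
#' @export
sas_thresholds <- function(sim_threshold = 0.35, act_threshold = 2.0) {
  stopifnot(is.numeric(sim_threshold), length(sim_threshold) == 1,
            sim_threshold > 0, sim_threshold < 1,
            is.numeric(act_threshold), length(act_threshold) == 1,
            act_threshold > 0)
  structure(list(sim_threshold = sim_threshold,
                 act_threshold = act_threshold),
            class = "sas_thresholds")
}

#' Assign SAS-map regions
#'
#' Region I (scaffold hops): dissimilar structures, similar activity.
#' Region II (smooth): similar structures, similar activity.
#' Region III (activity cliffs): similar structures, different activity.
#' Region IV (uncertain): dissimilar structures, different activity.
#'
#' @param tanimoto,activity_diff Numeric vectors (recycled to equal length).
#' @param thresholds A [sas_thresholds()] object.
#' @return Factor with levels `I`, `II`, `III`, `IV`.
#' @examples
#' assign_region(c(0.8, 0.1, 0.35), c(2.5, 0.3, 2), sas_thresholds())
#' @export
assign_region <- function(tanimoto, activity_diff,
                          thresholds = sas_thresholds()) {
  stopifnot(inherits(thresholds, "sas_thresholds"))
  similar <- tanimoto > thresholds$sim_threshold
  different <- activity_diff >= thresholds$act_threshold
  region <- ifelse(similar,
                   ifelse(different, "III", "II"),
                   ifelse(different, "IV", "I"))
  factor(region, levels = c("I", "II", "III", "IV"))
}

#' Extract activity cliffs from a pairwise table
#'
#' Activity cliffs are the region-III pairs: Tanimoto strictly above the
#' similarity threshold with an activity difference of at least the activity
#' threshold.
#'
#' @param pairs A [pairwise_table()] result.
#' @param thresholds A [sas_thresholds()] object.
#' @return Object of class `activity_cliffs`: list with `cliffs` (the
#'   region-III subset, with a `region` column), `n_unique_chemicals`,
#'   `region_counts` and `thresholds`.
#' @export
find_activity_cliffs <- function(pairs, thresholds = sas_thresholds()) {
  stopifnot(is.data.frame(pairs),
            all(c("id_i", "id_j", "tanimoto", "activity_diff") %in%
                  names(pairs)))
  region <- assign_region(pairs$tanimoto, pairs$activity_diff, thresholds)
  cliffs <- pairs[region == "III", , drop = FALSE]
  cliffs$region <- rep("III", nrow(cliffs))
  rownames(cliffs) <- NULL
  structure(list(
    cliffs = cliffs,
    n_unique_chemicals = length(unique(c(cliffs$id_i, cliffs$id_j))),
    region_counts = table(region),
    thresholds = thresholds
  ), class = "activity_cliffs")
}

#' @export
print.activity_cliffs <- function(x, ...) {
  cat("SAS-map activity cliffs:", nrow(x$cliffs), "pairs formed by",
      x$n_unique_chemicals, "unique chemicals\n")
  cat("  region counts:",
      paste(names(x$region_counts), as.integer(x$region_counts),
            sep = "=", collapse = " "), "\n")
  cat("  thresholds: similarity >", x$thresholds$sim_threshold,
      "; activity difference >=", x$thresholds$act_threshold, "\n")
  invisible(x)
}

#' Identify activity cliff generators (ACGs)
#'
#' An ACG is a chemical participating in at least `min_pairs` activity-cliff
#' pairs. Results are sorted by descending cliff-pair count, ties broken by
#' chemical identifier.
#'
#' @param cliffs An [find_activity_cliffs()] result, or its `cliffs`
#'   data.frame.
#' @param min_pairs Minimum cliff-pair count; default 5.
#' @return data.frame with `chem_id`, `cliff_pair_count`, `partners`
#'   (';'-joined partner ids).
#' @export
find_acgs <- function(cliffs, min_pairs = 5) {
  if (inherits(cliffs, "activity_cliffs")) cliffs <- cliffs$cliffs
  stopifnot(is.data.frame(cliffs), min_pairs >= 1)
  if (nrow(cliffs) == 0) {
    return(data.frame(chem_id = character(), cliff_pair_count = integer(),
                      partners = character(), stringsAsFactors = FALSE))
  }
  ids <- c(cliffs$id_i, cliffs$id_j)
  partners <- c(cliffs$id_j, cliffs$id_i)
  counts <- table(ids)
  keep <- names(counts)[counts >= min_pairs]
  out <- data.frame(
    chem_id = keep,
    cliff_pair_count = as.integer(counts[keep]),
    partners = vapply(keep, function(id)
      paste(sort(partners[ids == id]), collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$cliff_pair_count, out$chem_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render a SAS map
#'
#' Scatter of Tanimoto similarity (x) versus activity difference (y) for all
#' pairs, shaded by local point density, with the two threshold lines and the
#' four quadrant counts annotated.
#'
#' @param pairs A [pairwise_table()] result.
#' @param thresholds A [sas_thresholds()] object.
#' @param out_path Output image path; `.png` or `.svg`.
#' @param width,height Device size in pixels (png) or inches (svg).
#' @return Invisibly, `out_path`.
#' @export
render_sas_map <- function(pairs, thresholds = sas_thresholds(), out_path,
                           width = 1200, height = 900) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1)
  ext <- tolower(tools::file_ext(out_path))
  dir.create(dirname(out_path), showWarnings = FALSE, recursive = TRUE)
  if (ext == "png") {
    grDevices::png(out_path, width = width, height = height, res = 150)
  } else if (ext == "svg") {
    grDevices::svg(out_path, width = width / 150, height = height / 150)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  region <- assign_region(pairs$tanimoto, pairs$activity_diff, thresholds)
  counts <- table(region)
  ymax <- max(pairs$activity_diff, thresholds$act_threshold * 1.5)
  # density shading from a 2-D histogram (no KernSmooth dependency): each
  # point is coloured by the occupancy of its grid cell
  nb <- 100
  xi <- pmin(pmax(ceiling(pairs$tanimoto / (1 / nb)), 1), nb)
  yi <- pmin(pmax(ceiling(pairs$activity_diff / (ymax / nb)), 1), nb)
  cell <- xi + nb * (yi - 1L)
  occupancy <- table(cell)[as.character(cell)]
  pal <- grDevices::hcl.colors(64, "YlGnBu", rev = TRUE)
  level <- ceiling(64 * rank(occupancy, ties.method = "max") /
                     length(occupancy))
  graphics::plot(pairs$tanimoto, pairs$activity_diff,
                 xlim = c(0, 1), ylim = c(0, ymax),
                 pch = 16, cex = 0.45, col = pal[level],
                 xlab = "Tanimoto similarity (ECFP4)",
                 ylab = expression(Delta * "pAC"[50]),
                 main = "Structure-activity similarity map")
  graphics::abline(v = thresholds$sim_threshold, lty = 2)
  graphics::abline(h = thresholds$act_threshold, lty = 2)
  lab <- function(region, x, y) graphics::text(
    x, y, sprintf("%s: %d", region, as.integer(counts[region])), font = 2)
  xs <- thresholds$sim_threshold
  ys <- thresholds$act_threshold
  lab("I", xs / 2, ys / 2)
  lab("II", (1 + xs) / 2, ys / 2)
  lab("III", (1 + xs) / 2, (ymax + ys) / 2)
  lab("IV", xs / 2, (ymax + ys) / 2)
  invisible(out_path)
}
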