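#' Pipeline configuration
#'
#' Collects every tunable of the diagnosis pipeline; the full configuration
#' is echoed verbatim into every report.
#'
#' @param window,step Sliding-window width and step in query bp.
#' @param tau_attr Attribution threshold on the best per-species p-distance.
#' @param delta_margin Required margin between best and runner-up species.
#' @param min_run Minimum run of identically labelled windows.
#' @param bootstrap Number of bootstrap pseudoreplicates for marker trees.
#' @param min_support Minimum bootstrap support defining a placement clade.
#' @param seed Seed for the bootstrap resampler.
#' @param scan_policy Deletion policy inside scan windows (`"pairwise"` or
#'   `"complete"`).
#' @param tree_policy Deletion policy for tree distance matrices
#'   (`"complete"` or `"pairwise"`).
#' @param match,mismatch,gap_open,gap_extend Aligner scores.
#' @return A `run_config` list.
#' @export
diagnose_config <- function(window = 300, step = 50, tau_attr = 0.05,
                            delta_margin = 0.005, min_run = 2,
                            bootstrap = 1000, min_support = 70, seed = 1,
                            scan_policy = "pairwise",
                            tree_policy = "complete",
                            match = 1, mismatch = -1,
                            gap_open = -4, gap_extend = -1) {
  stopifnot(window >= 20, step >= 1, step <= window,
            tau_attr > 0, tau_attr < 1, delta_margin >= 0, min_run >= 1,
            bootstrap >= 1, min_support >= 0, min_support <= 100)
  structure(list(window = window, step = step, tau_attr = tau_attr,
                 delta_margin = delta_margin, min_run = min_run,
                 bootstrap = bootstrap, min_support = min_support,
                 seed = seed, scan_policy = scan_policy,
                 tree_policy = tree_policy, match = match,
                 mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "run_config")
}

#' Diagnose whether a query genome is a chimera of panel species
#'
#' Runs the full procedure: query-anchored panel alignment; per-marker
#' distance trees with bootstrap supports and nearest-species placements;
#' whole-genome sliding-window scan; window classification, segment merging
#' and informative-site breakpoint refinement; per-donor fractions. The
#' query is flagged as incongruent when marker placements are disjoint
#' across markers or when attribution finds two or more distinct donors.
#'
#' @param query Named character vector of length 1 (the query genome).
#' @param refs Named character vector of reference genomes (>= 2 species).
#' @param taxa Named character vector, reference id -> species label.
#' @param markers data.frame with columns gene, start, end, strand
#'   (1-based inclusive query coordinates).
#' @param config A `run_config`, see [diagnose_config()].
#' @return A `chimera_report`: list with `fractions`, `unattributed_pct`,
#'   `segments`, `breakpoints`, `marker_placements`,
#'   `marker_breakpoints` (genome breakpoints expressed in marker-local
#'   coordinates), `trees` (Newick strings with supports), `incongruent`,
#'   `config` and `version`.
#' @export
diagnose <- function(query, refs, taxa, markers, config = diagnose_config()) {
  stopifnot(inherits(config, "run_config"))
  refs <- refs[order(names(refs))]   # input-order invariance
  missing_ids <- setdiff(names(refs), names(taxa))
  if (length(missing_ids) > 0L)
    stop("reference(s) missing from taxon map: ", paste(missing_ids, collapse = ", "))
  if (length(unique(unname(taxa[names(refs)]))) < 2L)
    stop("reference panel must contain at least 2 species")
  validate_markers(markers)
  if (nrow(markers) < 1L) stop("need at least one marker")
  qid <- names(query) %||% "query"

  aln <- build_panel_alignment(query, refs, config$match, config$mismatch,
                               config$gap_open, config$gap_extend)
  L <- max(aln$col_pos)
  if (any(markers$end > L)) stop("marker coordinates exceed query length")

  # --- marker gene trees and placements ---
  trees <- list()
  for (k in seq_len(nrow(markers))) {
    cols <- which(aln$col_pos >= markers$start[k] & aln$col_pos <= markers$end[k])
    sub <- aln$mat[, cols, drop = FALSE]
    trees[[markers$gene[k]]] <- bootstrap_support(sub, B = config$bootstrap,
                                                  seed = config$seed + k)
  }
  placement <- placement_incongruence(trees, qid, taxa,
                                      min_support = config$min_support)

  # --- sliding-window attribution ---
  scan <- window_scan(aln, window = config$window, step = config$step,
                      policy = config$scan_policy)
  labels <- classify_windows(scan, taxa, tau_attr = config$tau_attr,
                             delta_margin = config$delta_margin)
  coarse <- merge_segments(labels, scan, min_run = config$min_run)
  refined <- refine_segments(aln, coarse, scan, taxa)
  fr <- attribution_fractions(refined$segments)

  donors <- sort(unique(refined$segments$label[
    refined$segments$label != "unattributed"]))
  incongruent <- placement$incongruent || length(donors) >= 2L

  marker_bps <- lapply(seq_len(nrow(markers)), function(k) {
    inside <- refined$breakpoints[refined$breakpoints >= markers$start[k] &
                                  refined$breakpoints < markers$end[k]]
    as.integer(inside - markers$start[k] + 1L)
  })
  names(marker_bps) <- markers$gene

  structure(list(
    query_id = qid,
    fractions = fr$fractions,
    fractions_raw = fr$fractions_raw,
    unattributed_pct = fr$unattributed_pct,
    unattributed_raw = fr$unattributed_raw,
    genome_length = L,
    donors = donors,
    segments = as.data.frame(refined$segments),
    breakpoints = refined$breakpoints,
    flagged_breakpoints = refined$flagged,
    marker_placements = placement$sets,
    marker_breakpoints = marker_bps,
    trees = vapply(trees, write_newick, character(1)),
    incongruent = incongruent,
    config = unclass(config),
    version = as.character(utils::packageVersion("chimeradx"))),
    class = "chimera_report")
}

#' @export
print.chimera_report <- function(x, ...) {
  cat("chimera_report for '", x$query_id, "' (", x$genome_length, " bp)\n",
      sep = "")
  cat("  incongruent/chimeric:", x$incongruent, "\n")
  for (d in names(x$fractions))
    cat(sprintf("  %-28s %5.1f%%\n", d, x$fractions[[d]]))
  cat(sprintf("  %-28s %5.1f%%\n", "unattributed", x$unattributed_pct))
  cat("  segments:\n")
  print(x$segments)
  for (g in names(x$marker_placements))
    cat("  ", g, " placement: {",
        paste(x$marker_placements[[g]], collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Write / read a diagnosis report as JSON
#'
#' The JSON round-trips all scalar fields, the segment table, breakpoints,
#' marker placements and the configuration echo.
#'
#' @param report A `chimera_report`.
#' @param path Output (input) path.
#' @return `path` invisibly; `read_report()` returns the report list.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "chimera_report"))
  out <- unclass(report)
  out$fractions <- as.list(report$fractions)
  out$fractions_raw <- as.list(report$fractions_raw)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  rep$fractions <- unlist(rep$fractions)
  rep$fractions_raw <- unlist(rep$fractions_raw)
  class(rep) <- "chimera_report"
  rep
}

#' Write the refined segment table as TSV
#'
#' @param report A `chimera_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(report, path) {
  utils::write.table(report$segments[, c("label", "start", "end", "mean_p")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
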