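#' Uncorrected p-distance between two aligned rows
#'
#' The p-distance is the proportion of differing sites among the compared
#' sites. A site is compared when both rows carry an unambiguous base
#' (A/C/G/T); gaps, N and other IUPAC ambiguity codes are treated as missing
#' data. Under the `"complete"` policy a precomputed mask of columns excluded
#' by complete deletion over the whole alignment is applied first.
#'
#' @param a,b Aligned rows of equal length: character vectors of single
#'   characters, or single strings.
#' @param policy `"pairwise"` (default) or `"complete"`.
#' @param mask Integer vector of column indices excluded by complete
#'   deletion (used with `policy = "complete"`).
#' @return List with `p` (proportion of differing sites, `NA` and flagged
#'   when no sites remain) and `n_sites` (number of compared sites).
#' @export
p_distance <- function(a, b, policy = c("pairwise", "complete"), mask = NULL) {
  policy <- match.arg(policy)
  if (length(a) == 1L && is.character(a)) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L && is.character(b)) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) stop("aligned rows differ in length")
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  if (policy == "complete" && length(mask) > 0L) ok[mask] <- FALSE
  n <- sum(ok)
  if (n == 0L) return(list(p = NA_real_, n_sites = 0L))
  list(p = sum(a[ok] != b[ok]) / n, n_sites = n)
}

complete_deletion_mask <- function(mat) {
  which(colSums(matrix(!(mat %in% DNA_BASES), nrow = nrow(mat))) > 0L)
}

#' All pairwise p-distances of an alignment
#'
#' Under `"complete"` deletion the mask of columns carrying a gap or missing
#' base in any row is computed once over all rows, so every pair is compared
#' on the same set of sites; under `"pairwise"` deletion missing sites are
#' dropped per pair.
#'
#' @param aln A `panel_alignment` or a character matrix (rows = sequences,
#'   one character per cell).
#' @param policy `"complete"` (default, matching complete deletion of
#'   positions with missing data) or `"pairwise"`.
#' @return A `p_dist_matrix`: list with `ids`, `d` (symmetric matrix of
#'   p-distances), `sites` (matrix of compared-site counts) and `policy`.
#' @export
distance_matrix <- function(aln, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  mat <- if (inherits(aln, "panel_alignment")) aln$mat else aln
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  n <- nrow(mat)
  if (n < 2L) stop("need at least two sequences")
  ids <- rownames(mat)
  mask <- if (policy == "complete") complete_deletion_mask(mat) else integer(0)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  s <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pd <- p_distance(mat[i, ], mat[j, ], policy = policy, mask = mask)
      if (pd$n_sites == 0L)
        stop("no comparable sites between '", ids[i], "' and '", ids[j], "'")
      d[i, j] <- d[j, i] <- pd$p
      s[i, j] <- s[j, i] <- pd$n_sites
    }
  }
  diag(s) <- if (policy == "complete") ncol(mat) - length(mask) else ncol(mat)
  structure(list(ids = ids, d = d, sites = s, policy = policy),
            class = "p_dist_matrix")
}

#' @export
print.p_dist_matrix <- function(x, ...) {
  cat("p_dist_matrix (", x$policy, " deletion), ", length(x$ids), " taxa\n", sep = "")
  print(round(x$d, 4))
  invisible(x)
}

#' Sliding-window p-distance scan of a query against a panel
#'
#' Slides a window along the query coordinates of a query-anchored panel
#' alignment and computes, per window, the p-distance from the query to
#' every reference. Windows advance by `step`; the last window is truncated
#' at the query end and kept when at least half a window long. Pairwise
#' deletion is the default within windows (complete deletion inside a short
#' window discards too much when any one reference has an indel).
#'
#' @param aln A `panel_alignment`.
#' @param window Window width in query bp (>= 20).
#' @param step Step between window starts, `1 <= step <= window`.
#' @param policy `"pairwise"` (default) or `"complete"`.
#' @return A `window_scan`: list with `starts`, `ends` (1-based inclusive
#'   query coordinates), `d` (windows x references p-distance matrix),
#'   `sites` (compared-site counts), `ref_ids`, `query_id`, `window`,
#'   `step`, `policy`.
#' @export
window_scan <- function(aln, window = 300, step = 50,
                        policy = c("pairwise", "complete")) {
  policy <- match.arg(policy)
  stopifnot(inherits(aln, "panel_alignment"))
  if (window < 20) stop("window must be >= 20 bp")
  if (step < 1 || step > window) stop("step must be in [1, window]")
  L <- max(aln$col_pos)
  if (L < window) {
    warning("query (", L, " bp) shorter than window (", window,
            " bp); using a single full-length window")
    starts <- 1L
    ends <- L
  } else {
    starts <- seq.int(1L, L - window + 1L, by = step)
    ends <- starts + window - 1L
    tail_start <- starts[length(starts)] + step
    if (tail_start <= L && (L - tail_start + 1L) >= window / 2) {
      starts <- c(starts, tail_start)
      ends <- c(ends, L)
    }
  }
  q <- aln$mat[aln$query_id, ]
  rids <- ref_ids(aln)
  nw <- length(starts)
  d <- matrix(NA_real_, nw, length(rids), dimnames = list(NULL, rids))
  s <- matrix(0L, nw, length(rids), dimnames = list(NULL, rids))
  mask <- if (policy == "complete") complete_deletion_mask(aln$mat) else integer(0)
  q_ok <- q %in% DNA_BASES
  if (length(mask) > 0L) q_ok[mask] <- FALSE
  for (r in rids) {
    rr <- aln$mat[r, ]
    ok <- q_ok & rr %in% DNA_BASES
    diff <- ok & q != rr
    cs_ok <- cumsum(ok)
    cs_diff <- cumsum(diff)
    # columns are sorted by query position; window [a,b] in query bp maps to
    # the column range via col_pos (identity for untrimmed alignments)
    lo <- findInterval(starts - 1L, aln$col_pos)   # last column strictly before start
    hi <- findInterval(ends, aln$col_pos)          # last column at or before end
    n_ok <- cs_ok[pmax(hi, 1L)] * (hi >= 1L) - c(0L, cs_ok)[lo + 1L]
    n_diff <- cs_diff[pmax(hi, 1L)] * (hi >= 1L) - c(0L, cs_diff)[lo + 1L]
    s[, r] <- n_ok
    d[, r] <- ifelse(n_ok > 0L, n_diff / n_ok, NA_real_)
  }
  structure(list(starts = starts, ends = ends, d = d, sites = s,
                 ref_ids = rids, query_id = aln$query_id,
                 window = window, step = step, policy = policy),
            class = "window_scan")
}

#' @export
print.window_scan <- function(x, ...) {
  cat("window_scan: ", length(x$starts), " window(s) of ", x$window,
      " bp (step ", x$step, ", ", x$policy, " deletion), ",
      length(x$ref_ids), " reference(s)\n", sep = "")
  invisible(x)
}

#' Export a window scan as a long-format data frame / TSV
#'
#' One row per window x reference.
#'
#' @param scan A `window_scan`.
#' @param path Optional TSV output path.
#' @return data.frame with columns start, end, ref, p, n_sites.
#' @export
scan_as_table <- function(scan, path = NULL) {
  stopifnot(inherits(scan, "window_scan"))
  nw <- length(scan$starts)
  out <- data.frame(
    start = rep(scan$starts, times = length(scan$ref_ids)),
    end = rep(scan$ends, times = length(scan$ref_ids)),
    ref = rep(scan$ref_ids, each = nw),
    p = as.vector(scan$d),
    n_sites = as.vector(scan$sites),
    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$ref), ]
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
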