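#' Global pairwise alignment with affine gap costs
#'
#' Needleman-Wunsch global alignment (Gotoh affine-gap variant, via
#' [Biostrings::pairwiseAlignment]) of two ungapped nucleotide sequences.
#' A gap of length k costs `gap_open + k * gap_extend` (penalties are given
#' as negative numbers). IUPAC ambiguity codes are scored by the fuzzy
#' nucleotide substitution matrix. Traceback is deterministic.
#'
#' @param a,b Ungapped nucleotide strings.
#' @param match Match score (default 1).
#' @param mismatch Mismatch score (default -1).
#' @param gap_open Gap opening penalty, <= 0 (default -4).
#' @param gap_extend Per-position gap extension penalty, <= 0 (default -1).
#' @return List with elements `a_aln`, `b_aln` (gapped strings of equal
#'   length) and `score`.
#' @export
global_align <- function(a, b, match = 1, mismatch = -1,
                         gap_open = -4, gap_extend = -1) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  if (grepl("-", a, fixed = TRUE) || grepl("-", b, fixed = TRUE))
    stop("input sequences must be ungapped")
  subm <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE, type = "DNA")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = subm,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend),
    type = "global")
  out <- list(a_aln = as.character(Biostrings::alignedPattern(pa)),
              b_aln = as.character(Biostrings::alignedSubject(pa)),
              score = Biostrings::score(pa))
  class(out) <- "pairwise_alignment"
  out
}

#' Build a query-anchored panel alignment
#'
#' Aligns every reference pairwise to the query and projects each aligned
#' reference onto the query's own coordinate system: the alignment has one
#' column per query position, a reference shows `-` where it is deleted
#' relative to the query, and reference insertions relative to the query are
#' recorded in `insertions` but masked (absent) from all query-coordinate
#' analyses. The query row always reproduces the input query exactly.
#'
#' @param query Named character vector of length 1 (the query genome), or an
#'   unnamed string (id defaults to `"query"`).
#' @param refs Named character vector of reference genomes.
#' @param match,mismatch,gap_open,gap_extend Alignment scores, see
#'   [global_align()].
#' @return A `panel_alignment`: list with `mat` (character matrix, rows =
#'   query then references, columns = query positions), `query_id`,
#'   `col_pos` (1-based query position of each column), `insertions`
#'   (per-reference data.frame of after_pos/seq).
#' @export
build_panel_alignment <- function(query, refs, match = 1, mismatch = -1,
                                  gap_open = -4, gap_extend = -1) {
  if (length(refs) < 1L) stop("need at least one reference sequence")
  qid <- names(query) %||% "query"
  if (is.null(names(query)) || !nzchar(qid)) qid <- "query"
  q <- unname(query[[1]])
  L <- nchar(q)
  mat <- matrix("-", nrow = length(refs) + 1L, ncol = L,
                dimnames = list(c(qid, names(refs)), NULL))
  mat[1L, ] <- strsplit(q, "")[[1]]
  insertions <- vector("list", length(refs))
  names(insertions) <- names(refs)
  for (i in seq_along(refs)) {
    al <- global_align(q, refs[[i]], match, mismatch, gap_open, gap_extend)
    qa <- strsplit(al$a_aln, "")[[1]]
    ra <- strsplit(al$b_aln, "")[[1]]
    anchored <- qa != "-"
    mat[i + 1L, ] <- ra[anchored]
    ins_idx <- which(!anchored)
    if (length(ins_idx) > 0L) {
      qpos <- cumsum(anchored)
      grp <- cumsum(c(1L, diff(ins_idx) != 1L))
      insertions[[i]] <- data.frame(
        after_pos = vapply(split(ins_idx, grp), function(ix) qpos[ix[1]], numeric(1)),
        seq = vapply(split(ins_idx, grp),
                     function(ix) paste(ra[ix], collapse = ""), character(1)),
        row.names = NULL, stringsAsFactors = FALSE)
    } else {
      insertions[[i]] <- data.frame(after_pos = numeric(0), seq = character(0))
    }
  }
  structure(list(mat = mat, query_id = qid, col_pos = seq_len(L),
                 insertions = insertions),
            class = "panel_alignment")
}

#' @export
print.panel_alignment <- function(x, ...) {
  cat("panel_alignment: query '", x$query_id, "', ",
      nrow(x$mat) - 1L, " reference(s), ", ncol(x$mat), " column(s)\n", sep = "")
  invisible(x)
}

aln_ids <- function(aln) rownames(aln$mat)

ref_ids <- function(aln) setdiff(rownames(aln$mat), aln$query_id)

#' Remove gapped and hyper-variable alignment columns
#'
#' A simplified divergent-column filter: a column is kept when the fraction
#' of rows carrying a gap or missing/ambiguous base is at most
#' `max_gap_frac` and the number of distinct unambiguous bases observed in
#' the column is at most `max_state_count`. Original query positions of the
#' retained columns stay available in `col_pos`.
#'
#' @param aln A `panel_alignment`.
#' @param max_gap_frac Maximum tolerated fraction of gap/missing characters
#'   per column (default 0, i.e. complete deletion of gapped columns).
#' @param max_state_count Maximum number of distinct unambiguous bases per
#'   column (default 4, i.e. no divergence filtering).
#' @return A `panel_alignment` restricted to the retained columns.
#' @export
trim_divergent_columns <- function(aln, max_gap_frac = 0, max_state_count = 4) {
  stopifnot(inherits(aln, "panel_alignment"))
  is_base <- matrix(aln$mat %in% DNA_BASES, nrow = nrow(aln$mat))
  gap_frac <- colMeans(!is_base)
  nstate <- vapply(seq_len(ncol(aln$mat)), function(j) {
    length(unique(aln$mat[is_base[, j], j]))
  }, integer(1))
  keep <- gap_frac <= max_gap_frac & nstate <= max_state_count
  if (!any(keep)) stop("empty alignment after trimming")
  aln$mat <- aln$mat[, keep, drop = FALSE]
  aln$col_pos <- aln$col_pos[keep]
  aln
}
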