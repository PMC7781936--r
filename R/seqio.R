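#' Read a nucleotide FASTA file
#'
#' Reads a FASTA file into a named character vector of uppercase nucleotide
#' sequences. `U` is mapped to `T` so RNA-style records can be compared
#' directly with DNA. Sequence ids are the first whitespace-delimited token
#' of each header line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector; names are sequence ids, values the
#'   uppercase sequences over the IUPAC alphabet (plus `-`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate id in FASTA file: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  names(seqs) <- ids
  validate_seqs(seqs)
  seqs
}

validate_seqs <- function(seqs) {
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[[i]])) stop("empty sequence for record '", names(seqs)[i], "'")
    bad <- setdiff(unique(strsplit(seqs[[i]], "")[[1]]), IUPAC_CHARS)
    if (length(bad) > 0L)
      stop("non-IUPAC character(s) ", paste(bad, collapse = ""),
           " in record '", names(seqs)[i], "'")
  }
  invisible(seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read a taxon map (sequence id to species label)
#'
#' Two-column TSV, header optional. Repeated ids with the same species are
#' collapsed; repeated ids with conflicting species are an error.
#'
#' @param path Path to a TSV file with columns id, species.
#' @return Named character vector mapping id to species label.
#' @export
read_taxon_map <- function(path) {
  if (!file.exists(path)) stop("taxon map not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no taxa in taxon map: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("taxon map must have two tab-separated columns: ", path)
  ids <- trimws(vapply(parts, `[[`, character(1), 1L))
  sp  <- trimws(vapply(parts, `[[`, character(1), 2L))
  # drop an optional header row
  if (tolower(ids[1]) %in% c("id", "seqid", "accession") ||
      tolower(sp[1]) %in% c("species", "taxon", "label")) {
    ids <- ids[-1]; sp <- sp[-1]
  }
  if (length(ids) == 0L) stop("no taxa in taxon map: ", path)
  map <- split(sp, ids)
  conf <- names(map)[vapply(map, function(x) length(unique(x)) > 1L, logical(1))]
  if (length(conf) > 0L)
    stop("id mapped to conflicting species in taxon map: ",
         paste(conf, collapse = ", "))
  out <- vapply(map, `[[`, character(1), 1L)
  out[unique(ids)]
}

#' Read a marker coordinate table
#'
#' A TSV with columns gene, start, end, strand (header optional). Coordinates
#' are 1-based inclusive. BED input (0-based half-open, columns
#' chrom/start/end/name/score/strand) is converted on read and the conversion
#' is reported via [message()].
#'
#' @param path Path to the marker table.
#' @param format `"tsv"` (gene/start/end/strand, 1-based inclusive) or
#'   `"bed"` (0-based half-open).
#' @return data.frame with columns gene, start, end, strand.
#' @export
read_marker_table <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("marker table not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(df) == 0L) stop("no markers in table: ", path)
  if (format == "bed") {
    if (ncol(df) < 3L) stop("BED marker table needs at least 3 columns")
    out <- data.frame(
      gene   = if (ncol(df) >= 4L) as.character(df[[4]]) else paste0("marker", seq_len(nrow(df))),
      start  = as.integer(df[[2]]) + 1L,
      end    = as.integer(df[[3]]),
      strand = if (ncol(df) >= 6L) as.character(df[[6]]) else "+",
      stringsAsFactors = FALSE)
    message("converted ", nrow(out), " BED interval(s) from 0-based half-open ",
            "to 1-based inclusive coordinates")
  } else {
    # drop an optional header row
    if (suppressWarnings(is.na(as.integer(df[1, 2])))) df <- df[-1, , drop = FALSE]
    if (nrow(df) == 0L) stop("no markers in table: ", path)
    if (ncol(df) < 3L) stop("marker table needs columns gene, start, end[, strand]")
    out <- data.frame(
      gene   = as.character(df[[1]]),
      start  = as.integer(df[[2]]),
      end    = as.integer(df[[3]]),
      strand = if (ncol(df) >= 4L) as.character(df[[4]]) else "+",
      stringsAsFactors = FALSE)
  }
  validate_markers(out)
  out
}

validate_markers <- function(m) {
  stopifnot(all(c("gene", "start", "end", "strand") %in% names(m)))
  if (any(is.na(m$start)) || any(is.na(m$end)))
    stop("non-numeric marker coordinates")
  if (any(m$start < 1L)) stop("marker start must be >= 1 (1-based inclusive)")
  if (any(m$end < m$start)) stop("marker end must be >= start")
  if (!all(m$strand %in% c("+", "-"))) stop("marker strand must be '+' or '-'")
  invisible(m)
}

#' Reverse-complement a nucleotide string
#'
#' Handles the full IUPAC alphabet and gap characters.
#'
#' @param seq Nucleotide string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", seq)
  vapply(comp, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

#' Extract a marker region from a sequence
#'
#' Coordinates are 1-based inclusive. Minus-strand markers are
#' reverse-complemented after extraction, so the returned sequence always
#' reads in the marker's coding orientation and has length `end - start + 1`.
#'
#' @param seq Single nucleotide string.
#' @param start,end 1-based inclusive coordinates on `seq`.
#' @param strand `"+"` or `"-"`.
#' @return Character scalar, the extracted (possibly reverse-complemented)
#'   subsequence.
#' @export
extract_marker <- function(seq, start, end, strand = "+") {
  stopifnot(length(seq) == 1L, is.character(seq))
  L <- nchar(seq)
  if (start < 1L || end > L || start > end)
    stop("marker coordinates [", start, ", ", end, "] out of range for a ",
         L, " bp sequence")
  sub <- substr(seq, start, end)
  if (strand == "-") sub <- revcomp(sub)
  sub
}

#' Write a phylogenetic tree as Newick
#'
#' Branch lengths and integer bootstrap supports (internal node labels) are
#' preserved. Every leaf must be named.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned instead of written.
#' @return Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (any(is.na(tree$tip.label)) || any(!nzchar(tree$tip.label)))
    stop("unnamed leaf in tree")
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
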