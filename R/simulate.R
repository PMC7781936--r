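#' Simulate sequences along a guide tree (Jukes-Cantor)
#'
#' The root sequence is uniform over A/C/G/T. Along each branch of length
#' `t` (expected substitutions per site, scaled by `mu`), every site
#' substitutes independently with probability `(3/4)(1 - exp(-4 t / 3))` to a
#' uniformly chosen different base. Reproducible given the seed.
#'
#' @param guide_tree An [ape::phylo] tree or a Newick string, with branch
#'   lengths in expected substitutions per site.
#' @param L Root sequence length (>= 1).
#' @param mu Rate multiplier applied to every branch (default 1).
#' @param seed Integer seed.
#' @return Named character vector of tip sequences (names = tip labels).
#' @export
evolve_sequences <- function(guide_tree, L, mu = 1, seed = 1) {
  if (is.character(guide_tree)) guide_tree <- ape::read.tree(text = guide_tree)
  stopifnot(inherits(guide_tree, "phylo"), L >= 1)
  if (is.null(guide_tree$edge.length)) stop("guide tree must have branch lengths")
  if (any(guide_tree$edge.length < 0)) stop("negative branch length in guide tree")
  set.seed(seed)
  ntip <- length(guide_tree$tip.label)
  nnode <- guide_tree$Nnode
  root <- ntip + 1L
  seqs <- vector("list", ntip + nnode)
  seqs[[root]] <- sample.int(4L, L, replace = TRUE)
  # parents precede children in a pruningwise-reversed edge ordering
  ord <- rev(ape::postorder(guide_tree))
  for (e in ord) {
    par <- guide_tree$edge[e, 1L]
    child <- guide_tree$edge[e, 2L]
    t <- mu * guide_tree$edge.length[e]
    p_sub <- 0.75 * (1 - exp(-4 * t / 3))
    s <- seqs[[par]]
    hit <- which(stats::runif(L) < p_sub)
    if (length(hit) > 0L) {
      # substitute to one of the three other bases, uniformly
      shift <- sample.int(3L, length(hit), replace = TRUE)
      s[hit] <- ((s[hit] - 1L + shift) %% 4L) + 1L
    }
    seqs[[child]] <- s
  }
  out <- vapply(seq_len(ntip),
                function(i) paste(DNA_BASES[seqs[[i]]], collapse = ""),
                character(1))
  names(out) <- guide_tree$tip.label
  out
}

#' Ground-truth segment table for a simulated mosaic
#'
#' @param start,end 1-based inclusive bounds.
#' @param label Donor species name, or `"novel"` for segments matching no
#'   donor.
#' @param L Genome length; segments must partition `1..L`.
#' @return A `scenario_truth` data.frame.
#' @export
scenario_truth <- function(start, end, label, L) {
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   label = as.character(label), stringsAsFactors = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (any(df$end < df$start)) stop("truth segment end before start")
  if (df$start[1L] != 1L || df$end[nrow(df)] != L ||
      (nrow(df) > 1L && any(df$start[-1L] != df$end[-nrow(df)] + 1L)))
    stop("truth segments must partition 1..L")
  attr(df, "genome_length") <- as.integer(L)
  class(df) <- c("scenario_truth", "data.frame")
  df
}

#' Build a mosaic (chimeric) query from donor genomes
#'
#' Every position of the query is copied verbatim from the donor that owns
#' it in the truth table. Positions inside `"novel"` segments are, with
#' probability `novel_rate` per site, resampled uniformly from the bases
#' differing from every donor at that site (guaranteeing unattributability
#' when `novel_rate` is high); otherwise they keep the first donor's base.
#'
#' @param donor_seqs Named character vector, species -> genome (all equal
#'   length, co-linear).
#' @param truth A `scenario_truth` whose donor labels name entries of
#'   `donor_seqs`.
#' @param novel_rate Per-site resampling probability inside novel segments
#'   (default 1).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return List with `query` (character string) and `truth`.
#' @export
make_chimera <- function(donor_seqs, truth, novel_rate = 1, seed = NULL) {
  stopifnot(inherits(truth, "scenario_truth"),
            novel_rate >= 0, novel_rate <= 1)
  lens <- nchar(donor_seqs)
  if (length(unique(lens)) != 1L) stop("donor genomes must be co-linear (equal length)")
  L <- attr(truth, "genome_length")
  if (lens[[1L]] != L) stop("donor length does not match truth genome length")
  donors <- setdiff(unique(truth$label), "novel")
  missing_d <- setdiff(donors, names(donor_seqs))
  if (length(missing_d) > 0L)
    stop("truth names unknown donor(s): ", paste(missing_d, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  dmat <- do.call(rbind, strsplit(unname(donor_seqs), ""))
  rownames(dmat) <- names(donor_seqs)
  q <- character(L)
  for (k in seq_len(nrow(truth))) {
    idx <- truth$start[k]:truth$end[k]
    if (truth$label[k] != "novel") {
      q[idx] <- dmat[truth$label[k], idx]
    } else {
      q[idx] <- dmat[1L, idx]
      hit <- idx[stats::runif(length(idx)) < novel_rate]
      for (i in hit) {
        avoid <- unique(dmat[, i])
        choices <- setdiff(DNA_BASES, avoid)
        if (length(choices) == 0L) choices <- DNA_BASES   # all four bases used by donors
        q[i] <- choices[sample.int(length(choices), 1L)]
      }
    }
  }
  list(query = paste(q, collapse = ""), truth = truth)
}

# force an informative site at each donor-segment boundary: all refs of the
# two species get distinct fixed bases at the given genome positions, so
# breakpoints are identifiable at nucleotide resolution by construction
plant_informative_sites <- function(panel, taxa, positions, species_a, species_b) {
  ids_a <- names(taxa)[taxa == species_a]
  ids_b <- names(taxa)[taxa == species_b]
  for (p in positions) {
    base_a <- substr(panel[[ids_a[1L]]], p, p)
    base_b <- DNA_BASES[match(base_a, DNA_BASES) %% 4L + 1L]
    for (id in ids_a) substr(panel[[id]], p, p) <- base_a
    for (id in ids_b) substr(panel[[id]], p, p) <- base_b
  }
  panel
}

#' Synthetic mirror of the published chimeric-mitogenome case
#'
#' Generates a labelled reference panel and a mosaic query reproducing the
#' structure of the documented chimeric bat mitogenome: genome length
#' 16,673 bp; donor species V contributing bp 1-14,301, 15,308-15,895 and
#' 16,151-16,673 (92.4%); donor species H contributing bp 14,308-15,294
#' (5.9%); novel (unattributable) sequence elsewhere, including the 243 bp
#' fragment at bp 15,908-16,150. The panel holds 2 V genomes, 3 H genomes
#' (about 0.5% within-species divergence, about 10% between V and H) and one
#' outgroup. Two markers are defined: a 698 bp "COI" interval inside the V
#' region and a 1,140 bp "cytb" interval straddling the V/H boundary at its
#' local bp 136/137. Donor bases at the four donor-segment boundary
#' positions are planted to differ between V and H, so the true breakpoints
#' are recoverable exactly from informative sites.
#'
#' @param seed Integer seed.
#' @param within_div Within-species tip-to-tip divergence (substitutions per
#'   site, default 0.005).
#' @param between_div One-way stem length separating V and H (default 0.06,
#'   giving ~10-11% p-distance between the species).
#' @param novel_rate Per-site resampling rate in novel segments (default 1).
#' @return List with `query` (named character vector of length 1), `panel`
#'   (named character vector), `taxa`, `markers` (data.frame), `truth`
#'   (`scenario_truth`), `seed` and `params`.
#' @export
paper_mirror_scenario <- function(seed = 1, within_div = 0.005,
                                  between_div = 0.06, novel_rate = 1) {
  L <- 16673L
  half <- within_div / 2
  nwk <- sprintf(
    "((V1:%f,V2:%f):%f,(H1:%f,(H2:%f,H3:%f):%f):%f,OUT1:%f);",
    half, half, between_div, half, half / 2, half / 2, half / 2,
    between_div, 2 * between_div)
  panel <- evolve_sequences(nwk, L = L, seed = seed)
  taxa <- c(V1 = "species_V", V2 = "species_V",
            H1 = "species_H", H2 = "species_H", H3 = "species_H",
            OUT1 = "outgroup_sp")
  truth <- scenario_truth(
    start = c(1L, 14302L, 14308L, 15295L, 15308L, 15896L, 16151L),
    end   = c(14301L, 14307L, 15294L, 15307L, 15895L, 16150L, 16673L),
    label = c("species_V", "novel", "species_H", "novel", "species_V",
              "novel", "species_V"),
    L = L)
  # donor-segment boundary flanks: last bp of each donor segment and first
  # bp of the adjacent donor segment
  panel <- plant_informative_sites(panel, taxa,
                                   positions = c(14301L, 14308L, 15294L, 15308L),
                                   species_a = "species_V",
                                   species_b = "species_H")
  chim <- make_chimera(c(species_V = unname(panel[["V1"]]),
                         species_H = unname(panel[["H1"]])),
                       truth, novel_rate = novel_rate)
  markers <- data.frame(
    gene = c("COI", "cytb"),
    start = c(5001L, 14166L),
    end = c(5698L, 15305L),
    strand = c("+", "+"),
    stringsAsFactors = FALSE)
  list(query = c(query = chim$query), panel = panel, taxa = taxa,
       markers = markers, truth = truth, seed = seed,
       params = list(within_div = within_div, between_div = between_div,
                     novel_rate = novel_rate, L = L))
}

#' Write a simulated scenario to disk
#'
#' Writes `query.fasta`, `refs.fasta`, `taxa.tsv`, `markers.tsv` and
#' `truth.json` into a directory, in the formats consumed by the
#' command-line interface.
#'
#' @param scenario Output of [paper_mirror_scenario()] (or a list with the
#'   same fields).
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(scenario$query, file.path(dir, "query.fasta"))
  write_fasta(scenario$panel, file.path(dir, "refs.fasta"))
  utils::write.table(
    data.frame(id = names(scenario$taxa), species = unname(scenario$taxa)),
    file.path(dir, "taxa.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(scenario$markers, file.path(dir, "markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  truth <- list(seed = scenario$seed, params = scenario$params,
                segments = as.data.frame(scenario$truth))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
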