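#' Neighbor-joining tree from a p-distance matrix
#'
#' Standard Q-criterion neighbor joining (via [ape::nj]); negative branch
#' lengths are clamped to zero. The returned tree is unrooted.
#'
#' @param dm A `p_dist_matrix` or a symmetric numeric matrix with dimnames.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "p_dist_matrix")) dm$d else dm
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(is.na(d))) stop("undefined distances in matrix")
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# distance matrix (complete deletion) from an integer-coded or character
# alignment matrix, for bootstrap replicates; returns NULL when some pair
# has no comparable sites
try_dist <- function(mat) {
  tryCatch(distance_matrix(mat, policy = "complete"),
           error = function(e) NULL)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the full-data NJ tree from complete-deletion p-distances, then
#' resamples alignment columns with replacement `B` times, rebuilds the NJ
#' tree for each pseudoreplicate, and maps bipartition frequencies (as
#' percentages of usable replicates) onto the internal nodes of the
#' full-data tree. Replicates in which some pair has no comparable sites are
#' skipped (counted and warned about).
#'
#' @param aln A `panel_alignment` or character matrix (rows = sequences).
#' @param B Number of bootstrap pseudoreplicates (>= 1; 1000 in routine use).
#' @param seed Integer seed for the column resampler.
#' @return An [ape::phylo] tree whose `node.label` holds integer supports in
#'   `[0, 100]` (the root label is `NA`).
#' @export
bootstrap_support <- function(aln, B = 1000, seed = 1) {
  stopifnot(B >= 1)
  mat <- if (inherits(aln, "panel_alignment")) aln$mat else aln
  main <- nj_tree(distance_matrix(mat, policy = "complete"))
  if (length(unique(apply(mat, 2L, paste, collapse = ""))) == 1L)
    warning("alignment has zero variable sites; bootstrap supports are degenerate")
  set.seed(seed)
  nc <- ncol(mat)
  boot_trees <- vector("list", B)
  skipped <- 0L
  for (b in seq_len(B)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    dm <- try_dist(mat[, cols, drop = FALSE])
    if (is.null(dm)) { skipped <- skipped + 1L; next }
    boot_trees[[b]] <- nj_tree(dm)
  }
  boot_trees <- boot_trees[!vapply(boot_trees, is.null, logical(1))]
  if (skipped > 0L)
    warning(skipped, " bootstrap replicate(s) skipped (pair with no comparable sites)")
  if (length(boot_trees) == 0L) stop("all bootstrap replicates failed")
  counts <- ape::prop.clades(main, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- as.integer(round(100 * counts / length(boot_trees)))
  supports <- pmin(pmax(supports, 0L), 100L)
  main$node.label <- supports
  main$node.label[1L] <- NA_integer_   # root of the stored representation
  main
}

# tip-label sets of every internal node, in node order (root first)
node_tip_sets <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  lapply(pp, function(ix) labs[ix])
}

#' Nearest-species set of a query leaf in a supported tree
#'
#' The species labels of the other leaves in the smallest clade (over both
#' orientations of every internal bipartition with support at least
#' `min_support`) that contains the query and at least one other leaf.
#' Equal-size candidate clades are broken by the mean patristic distance
#' from the query to the clade's other members, so the query's genuinely
#' nearest neighbours win. When no supported bipartition qualifies, the full
#' leaf set is used.
#'
#' @param tree An [ape::phylo] tree with integer supports in `node.label`.
#' @param query_id Tip label of the query.
#' @param taxa Named id -> species map for the non-query leaves.
#' @param min_support Minimum bootstrap support for a bipartition to define
#'   a clade (default 70).
#' @return Character vector of species labels (query excluded).
#' @export
nearest_species_set <- function(tree, query_id, taxa, min_support = 70) {
  if (!(query_id %in% tree$tip.label)) stop("query '", query_id, "' absent from tree")
  all_tips <- tree$tip.label
  sets <- node_tip_sets(tree)
  supports <- tree$node.label %||% rep(NA_integer_, tree$Nnode)
  pat <- ape::cophenetic.phylo(tree)
  mean_pat <- function(side) mean(pat[query_id, setdiff(side, query_id)])
  best <- all_tips   # fallback: the whole tree
  best_pat <- mean_pat(best)
  for (k in seq_along(sets)[-1L]) {       # skip the root (trivial bipartition)
    s <- suppressWarnings(as.integer(supports[k]))
    if (is.na(s) || s < min_support) next
    side <- if (query_id %in% sets[[k]]) sets[[k]] else setdiff(all_tips, sets[[k]])
    if (length(side) < 2L || !(query_id %in% side)) next
    mp <- mean_pat(side)
    if (length(side) < length(best) ||
        (length(side) == length(best) && mp < best_pat)) {
      best <- side
      best_pat <- mp
    }
  }
  others <- setdiff(best, query_id)
  sort(unique(unname(taxa[others])))
}

#' Placement incongruence across marker trees
#'
#' For each marker tree the query's nearest-species set is computed with
#' [nearest_species_set()]; the placements are incongruent when some pair of
#' markers yields disjoint sets — the primary tree-based chimera signal.
#' Overlapping sets are not flagged (a consistent placement away from the
#' nominal species indicates misidentification, not chimerism).
#'
#' @param trees Named list of [ape::phylo] trees (one per marker).
#' @param query_id Tip label of the query, present in every tree.
#' @param taxa Named id -> species map.
#' @param min_support Support threshold, see [nearest_species_set()].
#' @return List with `sets` (named list, marker -> species set) and
#'   `incongruent` (logical).
#' @export
placement_incongruence <- function(trees, query_id, taxa, min_support = 70) {
  stopifnot(is.list(trees), length(trees) >= 1L)
  sets <- lapply(trees, nearest_species_set, query_id = query_id,
                 taxa = taxa, min_support = min_support)
  incong <- FALSE
  if (length(sets) >= 2L) {
    for (i in seq_len(length(sets) - 1L)) {
      for (j in (i + 1L):length(sets)) {
        if (length(intersect(sets[[i]], sets[[j]])) == 0L) incong <- TRUE
      }
    }
  }
  list(sets = sets, incongruent = incong)
}
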