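#' Summarize a window scan per species
#'
#' Per window and species, the distance to a species is the minimum
#' p-distance over that species' references (a query should be compared with
#' its best conspecific representative).
#'
#' @param scan A `window_scan`.
#' @param taxa Named character vector mapping reference id to species label.
#' @return Matrix windows x species of per-species minimum p-distances
#'   (`Inf` where no reference of a species was comparable).
#' @export
species_distances <- function(scan, taxa) {
  stopifnot(inherits(scan, "window_scan"))
  missing_ids <- setdiff(scan$ref_ids, names(taxa))
  if (length(missing_ids) > 0L)
    stop("reference(s) missing from taxon map: ",
         paste(missing_ids, collapse = ", "))
  sp <- sort(unique(unname(taxa[scan$ref_ids])))
  out <- matrix(Inf, nrow = nrow(scan$d), ncol = length(sp),
                dimnames = list(NULL, sp))
  for (s in sp) {
    cols <- scan$ref_ids[taxa[scan$ref_ids] == s]
    m <- scan$d[, cols, drop = FALSE]
    v <- suppressWarnings(apply(m, 1L, min, na.rm = TRUE))
    out[, s] <- ifelse(is.finite(v), v, Inf)
  }
  out
}

#' Label scan windows with a donor species
#'
#' A window is attributed to the species with the smallest distance when that
#' distance is at most `tau_attr` and the runner-up species is at least
#' `delta_margin` further away; otherwise the window is `"unattributed"`.
#' Ties between species are broken by lexicographic species name.
#'
#' @param scan A `window_scan`.
#' @param taxa Named character vector id -> species.
#' @param tau_attr Attribution threshold on the best per-species p-distance
#'   (default 0.05).
#' @param delta_margin Required margin between best and runner-up species
#'   (default 0.005).
#' @return A `window_labels`: list with `labels` (character per window),
#'   `species_d` (windows x species distance matrix), and the thresholds.
#' @export
classify_windows <- function(scan, taxa, tau_attr = 0.05, delta_margin = 0.005) {
  stopifnot(tau_attr > 0, tau_attr < 1, delta_margin >= 0)
  spd <- species_distances(scan, taxa)
  if (nrow(spd) == 0L) stop("empty window scan")
  labels <- apply(spd, 1L, function(v) {
    o <- order(v, names(v))          # ties -> lexicographic species order
    best <- v[o[1]]
    runner <- if (length(v) >= 2L) v[o[2]] else Inf
    if (is.finite(best) && best <= tau_attr && (runner - best) >= delta_margin)
      names(v)[o[1]] else "unattributed"
  })
  structure(list(labels = unname(labels), species_d = spd,
                 tau_attr = tau_attr, delta_margin = delta_margin),
            class = "window_labels")
}

#' Construct a segment table
#'
#' Segments are 1-based inclusive query intervals, ordered and
#' non-overlapping. Gaps between segments are allowed and are counted as
#' unattributed by [attribution_fractions()], mirroring submissions where
#' short stretches match no donor.
#'
#' @param start,end Integer vectors of 1-based inclusive bounds.
#' @param label Character vector of donor species or `"unattributed"`.
#' @param genome_length Total query length L.
#' @param mean_p Optional per-segment mean distance to the labelled donor.
#' @return A `segment_attribution` data.frame with attribute
#'   `genome_length`.
#' @export
segment_attribution <- function(start, end, label, genome_length,
                                mean_p = NA_real_) {
  stopifnot(length(start) == length(end), length(start) == length(label))
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   label = as.character(label),
                   mean_p = rep_len(mean_p, length(start)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (any(df$end < df$start)) stop("segment end before start")
  if (nrow(df) > 1L && any(df$start[-1L] <= df$end[-nrow(df)]))
    stop("overlapping segments")
  if (any(df$start < 1L) || any(df$end > genome_length))
    stop("segments exceed genome bounds [1, ", genome_length, "]")
  attr(df, "genome_length") <- as.integer(genome_length)
  class(df) <- c("segment_attribution", "data.frame")
  df
}

#' Merge labelled windows into coarse segments
#'
#' Maximal runs of identically labelled windows become segments. Runs
#' shorter than `min_run` windows are absorbed into the longer flanking run
#' (ties go left). Provisional segment bounds are midpoints between the
#' centres of discordant adjacent windows; they are refined later from
#' informative sites.
#'
#' @param labels A `window_labels` or plain character vector of per-window
#'   labels.
#' @param scan The `window_scan` the labels came from.
#' @param min_run Minimum run length in windows (default 2).
#' @return A `segment_attribution` with attributes `win_from`/`win_to`
#'   giving each segment's window-index range.
#' @export
merge_segments <- function(labels, scan, min_run = 2) {
  if (inherits(labels, "window_labels")) labels <- labels$labels
  stopifnot(length(labels) == length(scan$starts), min_run >= 1)
  lab <- labels
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_run)
    if (length(short) == 0L) break
    k <- short[1L]
    left_len <- if (k > 1L) r$lengths[k - 1L] else -1L
    right_len <- if (k < length(r$lengths)) r$lengths[k + 1L] else -1L
    new_lab <- if (left_len >= right_len) r$values[k - 1L] else r$values[k + 1L]
    idx <- (sum(r$lengths[seq_len(k - 1L)]) + 1L):sum(r$lengths[seq_len(k)])
    lab[idx] <- new_lab
  }
  r <- rle(lab)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- c(1L, ends_idx[-length(ends_idx)] + 1L)
  L <- scan$ends[length(scan$ends)]
  centre <- (scan$starts + scan$ends) / 2
  seg_start <- integer(length(r$values))
  seg_end <- integer(length(r$values))
  for (k in seq_along(r$values)) {
    seg_start[k] <- if (k == 1L) 1L else
      as.integer(floor((centre[ends_idx[k - 1L]] + centre[starts_idx[k]]) / 2)) + 1L
    seg_end[k] <- if (k == length(r$values)) L else
      as.integer(floor((centre[ends_idx[k]] + centre[starts_idx[k + 1L]]) / 2))
  }
  seg <- segment_attribution(seg_start, seg_end, r$values, L)
  attr(seg, "win_from") <- starts_idx
  attr(seg, "win_to") <- ends_idx
  seg
}

# integer-coded rows of the panel alignment restricted to a query interval;
# returns query positions and the (query, left, right) characters
interval_cols <- function(aln, lo, hi) {
  sel <- aln$col_pos >= lo & aln$col_pos <= hi
  list(pos = aln$col_pos[sel], idx = which(sel))
}

#' Refine a donor-switch breakpoint from informative sites
#'
#' Over the search interval, informative sites are the columns where the two
#' donor rows differ and the query matches exactly one of them. The left
#' boundary `b` (last bp of the left segment) maximizes the number of
#' left-matching sites at or before `b` plus right-matching sites after `b`,
#' ties broken towards the smallest `b`. The symmetric right boundary `r`
#' (first bp of the right segment) is computed with ties towards the largest
#' `r`; when `r > b + 1` the query matches neither donor in between and the
#' gap is preserved as unattributed rather than silently assigned.
#'
#' @param aln A `panel_alignment`.
#' @param left_donor,right_donor Reference ids of the two donors (distinct).
#' @param search_interval Integer vector `c(lo, hi)` of query coordinates
#'   spanning the discordant windows.
#' @return List with `b` (last bp of the left segment), `r` (first bp of the
#'   right segment), `flagged` (`TRUE` when no informative site was found and
#'   the provisional midpoint was used) and `n_informative`.
#' @export
refine_breakpoint <- function(aln, left_donor, right_donor, search_interval) {
  stopifnot(inherits(aln, "panel_alignment"),
            left_donor != right_donor,
            length(search_interval) == 2L)
  lo <- search_interval[1L]; hi <- search_interval[2L]
  cols <- interval_cols(aln, lo, hi)
  q <- aln$mat[aln$query_id, cols$idx]
  dl <- aln$mat[left_donor, cols$idx]
  dr <- aln$mat[right_donor, cols$idx]
  ok <- q %in% DNA_BASES & dl %in% DNA_BASES & dr %in% DNA_BASES
  inf_site <- ok & dl != dr & xor(q == dl, q == dr)
  pos <- cols$pos[inf_site]
  match_left <- (q == dl)[inf_site]
  if (length(pos) == 0L) {
    mid <- as.integer(floor((lo + hi) / 2))
    return(list(b = mid, r = mid + 1L, flagged = TRUE, n_informative = 0L))
  }
  # score(b) = #L sites <= b  +  #R sites > b, piecewise constant in b;
  # evaluate at candidate boundaries lo-1 and each informative site
  cand_b <- c(lo - 1L, pos)
  cum_l <- c(0L, cumsum(match_left))
  cum_r <- c(0L, cumsum(!match_left))
  tot_r <- sum(!match_left)
  idx <- seq_along(cand_b)              # cand_b[k] has k-1 sites at/before it
  score_b <- cum_l[idx] + (tot_r - cum_r[idx])
  b <- cand_b[which.max(score_b)]       # which.max takes the first (smallest b)
  # score(r) = #L sites < r  +  #R sites >= r, ties -> largest r
  cand_r <- c(pos, hi + 1L)
  score_r <- cum_l[idx] + (tot_r - cum_r[idx])
  r <- cand_r[max(which(score_r == max(score_r)))]
  if (r <= b) r <- b + 1L
  list(b = as.integer(b), r = as.integer(r), flagged = FALSE,
       n_informative = length(pos))
}

#' Refine the edge between a donor segment and unattributed sequence
#'
#' Weighted change-point in the agreement between query and donor over the
#' interval: each comparable site scores `+1` when query and donor agree and
#' `-edge_weight` when they disagree, and the boundary maximizes the summed
#' score assigned to the donor side. With the default weight 3 a stretch
#' counts as donor-like only above 75% identity, comfortably above the
#' chance identity of unattributable sequence (whose pairwise alignment to
#' the donor can produce runs of coincidental matches) and below the
#' identity of genuine donor sequence. For a `"left"` edge the last
#' donor-side position `b` is returned (ties smallest); for a `"right"`
#' edge, the first position `r` of renewed agreement (ties largest).
#'
#' @param aln A `panel_alignment`.
#' @param donor Reference id of the flanking donor.
#' @param search_interval `c(lo, hi)` query coordinates.
#' @param side `"left"` (donor on the left) or `"right"`.
#' @param edge_weight Penalty weight on disagreements (default 3).
#' @return List with `pos` (boundary: last donor bp for `"left"`, first
#'   donor bp for `"right"`) and `flagged`.
#' @export
refine_edge <- function(aln, donor, search_interval, side = c("left", "right"),
                        edge_weight = 3) {
  side <- match.arg(side)
  lo <- search_interval[1L]; hi <- search_interval[2L]
  cols <- interval_cols(aln, lo, hi)
  q <- aln$mat[aln$query_id, cols$idx]
  d <- aln$mat[donor, cols$idx]
  # a gap in the donor row is evidence against donor identity at that query
  # position, so it scores as a disagreement; ambiguity codes stay neutral
  ok <- q %in% DNA_BASES & (d %in% DNA_BASES | d == "-")
  pos <- cols$pos[ok]
  agree <- (q == d)[ok]
  if (length(pos) == 0L) {
    mid <- as.integer(floor((lo + hi) / 2))
    return(list(pos = if (side == "left") mid else mid + 1L, flagged = TRUE))
  }
  z <- ifelse(agree, 1, -edge_weight)
  cum_z <- c(0, cumsum(z))
  idx <- seq_len(length(pos) + 1L)
  if (side == "left") {
    # donor side is <= b: maximize prefix score, ties -> smallest b
    cand <- c(lo - 1L, pos)
    out <- cand[which.max(cum_z[idx])]
  } else {
    # donor side is >= r: maximize suffix score, ties -> largest r
    cand <- c(pos, hi + 1L)
    sc <- cum_z[length(cum_z)] - cum_z[idx]
    out <- cand[max(which(sc == max(sc)))]
  }
  list(pos = as.integer(out), flagged = FALSE)
}

# best reference of a species over a query interval (min p-distance over the
# segment interior, ties broken by reference id so results are
# input-order invariant)
best_ref_of_species <- function(aln, taxa, species, lo, hi) {
  cands <- sort(ref_ids(aln)[taxa[ref_ids(aln)] == species])
  idx <- interval_cols(aln, lo, hi)$idx
  q <- aln$mat[aln$query_id, idx]
  p <- vapply(cands, function(id) {
    pd <- p_distance(q, aln$mat[id, idx])
    if (is.na(pd$p)) Inf else pd$p
  }, numeric(1))
  cands[which.min(p)]
}

#' Refine coarse segments to nucleotide-resolution boundaries
#'
#' Each transition between coarse segments is refined: donor-to-donor
#' junctions (including those separated by an unattributed run, when the
#' flanking donors differ) use two-donor informative sites via
#' [refine_breakpoint()]; junctions between a donor and unattributed
#' sequence flanked by the same donor (or at the genome ends) use the
#' one-donor agreement change-point via [refine_edge()]. Unattributed gaps
#' between refined donor boundaries are preserved.
#'
#' @param aln A `panel_alignment`.
#' @param coarse A `segment_attribution` from [merge_segments()] (with
#'   window ranges attached).
#' @param scan The `window_scan`.
#' @param taxa Named id -> species map.
#' @return List with `segments` (refined `segment_attribution`),
#'   `breakpoints` (ends of all segments but the last) and `flagged`
#'   (breakpoints that fell back to provisional midpoints).
#' @export
refine_segments <- function(aln, coarse, scan, taxa) {
  L <- attr(coarse, "genome_length")
  wf <- attr(coarse, "win_from"); wt <- attr(coarse, "win_to")
  lab <- coarse$label
  k <- nrow(coarse)
  out_start <- integer(0); out_end <- integer(0); out_lab <- character(0)
  flagged <- integer(0)
  cur <- 1L
  i <- 1L
  emit <- function(s, e, l) {
    if (e >= s) {
      out_start <<- c(out_start, s); out_end <<- c(out_end, e)
      out_lab <<- c(out_lab, l)
    }
  }
  while (i < k) {
    li <- lab[i]
    lj <- lab[i + 1L]
    if (li != "unattributed" && lj != "unattributed") {
      interval <- c(scan$starts[wt[i]], scan$ends[wf[i + 1L]])
      bp <- refine_breakpoint(aln,
                              best_ref_of_species(aln, taxa, li, coarse$start[i], coarse$end[i]),
                              best_ref_of_species(aln, taxa, lj, coarse$start[i + 1L], coarse$end[i + 1L]),
                              interval)
      b <- max(bp$b, cur); r <- max(bp$r, b + 1L)
      if (bp$flagged) flagged <- c(flagged, b)
      emit(cur, b, li)
      emit(b + 1L, r - 1L, "unattributed")
      cur <- r
      i <- i + 1L
    } else if (li != "unattributed" && lj == "unattributed" &&
               i + 2L <= k && lab[i + 2L] != "unattributed" &&
               lab[i + 2L] != li) {
      # donor | unattributed run | different donor: refine across the run
      interval <- c(scan$starts[wt[i]], scan$ends[wf[i + 2L]])
      bp <- refine_breakpoint(aln,
                              best_ref_of_species(aln, taxa, li, coarse$start[i], coarse$end[i]),
                              best_ref_of_species(aln, taxa, lab[i + 2L],
                                                  coarse$start[i + 2L], coarse$end[i + 2L]),
                              interval)
      b <- max(bp$b, cur); r <- max(bp$r, b + 1L)
      if (bp$flagged) flagged <- c(flagged, b)
      emit(cur, b, li)
      emit(b + 1L, r - 1L, "unattributed")
      cur <- r
      i <- i + 2L
    } else if (li != "unattributed" && lj == "unattributed") {
      interval <- c(scan$starts[wt[i]], scan$ends[wf[i + 1L]])
      ed <- refine_edge(aln,
                        best_ref_of_species(aln, taxa, li, coarse$start[i], coarse$end[i]),
                        interval, side = "left")
      b <- max(ed$pos, cur)
      if (ed$flagged) flagged <- c(flagged, b)
      emit(cur, b, li)
      cur <- b + 1L
      i <- i + 1L
    } else {
      # unattributed | donor
      interval <- c(scan$starts[wt[i]], scan$ends[wf[i + 1L]])
      ed <- refine_edge(aln,
                        best_ref_of_species(aln, taxa, lj, coarse$start[i + 1L], coarse$end[i + 1L]),
                        interval, side = "right")
      r <- max(ed$pos, cur + 1L)
      if (ed$flagged) flagged <- c(flagged, r - 1L)
      emit(cur, r - 1L, "unattributed")
      cur <- r
      i <- i + 1L
    }
  }
  emit(cur, L, lab[k])
  mean_p <- segment_mean_p(aln, out_start, out_end, out_lab, scan, taxa)
  seg <- segment_attribution(out_start, out_end, out_lab, L, mean_p = mean_p)
  bps <- seg$end[-nrow(seg)]
  list(segments = seg, breakpoints = as.integer(bps), flagged = flagged)
}

segment_mean_p <- function(aln, starts, ends, labels, scan, taxa) {
  sp_all <- sort(unique(unname(taxa[ref_ids(aln)])))
  vapply(seq_along(starts), function(k) {
    cols <- interval_cols(aln, starts[k], ends[k])$idx
    if (length(cols) == 0L) return(NA_real_)
    q <- aln$mat[aln$query_id, cols]
    target_sp <- if (labels[k] == "unattributed") sp_all else labels[k]
    best <- Inf
    for (s in target_sp) {
      for (rid in ref_ids(aln)[taxa[ref_ids(aln)] == s]) {
        pd <- p_distance(q, aln$mat[rid, cols])
        if (!is.na(pd$p) && pd$p < best) best <- pd$p
      }
    }
    if (is.finite(best)) best else NA_real_
  }, numeric(1))
}

round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Per-donor genome fractions from a segment table
#'
#' For each donor label, the summed segment length divided by the genome
#' length, as a percentage rounded half-up to one decimal. Positions covered
#' by no segment (inter-segment gaps) and positions in segments labelled
#' `"unattributed"` both count towards the unattributed percentage. Raw
#' (unrounded) values are returned alongside.
#'
#' @param seg A `segment_attribution`.
#' @return List with `fractions` (named, rounded, donors only),
#'   `unattributed_pct` (rounded), `fractions_raw`, `unattributed_raw` and
#'   `genome_length`.
#' @export
attribution_fractions <- function(seg) {
  stopifnot(inherits(seg, "segment_attribution"))
  L <- attr(seg, "genome_length")
  lens <- seg$end - seg$start + 1L
  if (sum(lens) > L) stop("segments exceed genome length")
  donors <- sort(unique(seg$label[seg$label != "unattributed"]))
  raw <- vapply(donors, function(d) 100 * sum(lens[seg$label == d]) / L,
                numeric(1))
  unatt_raw <- 100 - sum(raw)
  list(fractions = round_half_up(raw, 1),
       unattributed_pct = round_half_up(unatt_raw, 1),
       fractions_raw = raw,
       unattributed_raw = unatt_raw,
       genome_length = L)
}
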