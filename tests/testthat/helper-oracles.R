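# independent oracles used across tests

# exhaustive global-alignment score: enumerates every alignment of a and b,
# scoring a gap of length k as gap_open + k * gap_extend (affine)
brute_force_align_score <- function(a, b, match = 1, mismatch = -1,
                                    gap_open = -4, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "d"))
    }
    if (i <= length(av)) {   # gap in b
      g <- gap_extend + if (prev == "u") 0 else gap_open
      best <- max(best, g + rec(i + 1L, j, "u"))
    }
    if (j <= length(bv)) {   # gap in a
      g <- gap_extend + if (prev == "l") 0 else gap_open
      best <- max(best, g + rec(i, j + 1L, "l"))
    }
    best
  }
  rec(1L, 1L, "s")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# mismatch-count p-distance oracle on two ungapped equal-length strings
oracle_p <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  list(p = sum(av[ok] != bv[ok]) / sum(ok), n = sum(ok))
}

# two co-linear donor sequences at roughly `div` divergence with an
# informative site planted at the boundary flanks b and b+1
make_donor_pair <- function(L, div = 0.05) {
  d1 <- strsplit(random_dna(L), "")[[1]]
  d2 <- d1
  flip <- which(runif(L) < div)
  d2[flip] <- vapply(d1[flip], function(x) {
    sample(setdiff(c("A", "C", "G", "T"), x), 1L)
  }, character(1))
  list(d1 = d1, d2 = d2)
}

plant_flank_difference <- function(pair, pos) {
  for (p in pos) {
    if (pair$d1[p] == pair$d2[p])
      pair$d2[p] <- setdiff(c("A", "C", "G", "T"), pair$d1[p])[1]
  }
  pair
}

# tiny two-species panel plus a conspecific (non-chimeric) query, for
# pure-sample controls; returns what diagnose() needs
small_pure_scenario <- function(seed, L = 2000) {
  nwk <- "(((A1:0.0025,A2:0.0025):0.001,Q:0.0035):0.06,(B1:0.0025,B2:0.0025):0.06);"
  tips <- evolve_sequences(nwk, L = L, seed = seed)
  list(query = c(Q = unname(tips[["Q"]])),
       refs = tips[c("A1", "A2", "B1", "B2")],
       taxa = c(A1 = "species_A", A2 = "species_A",
                B1 = "species_B", B2 = "species_B"),
       markers = data.frame(gene = "m1", start = 501L, end = 1000L,
                            strand = "+", stringsAsFactors = FALSE))
}

# small two-donor mosaic scenario with one switch at `b`, for end-to-end
# chimera checks at modest problem sizes
small_mosaic_scenario <- function(seed, L = 2000, b = 1000) {
  nwk <- "((A1:0.0025,A2:0.0025):0.06,(B1:0.0025,B2:0.0025):0.06);"
  tips <- evolve_sequences(nwk, L = L, seed = seed)
  a1 <- strsplit(tips[["A1"]], "")[[1]]
  b1 <- strsplit(tips[["B1"]], "")[[1]]
  if (a1[b] == b1[b]) b1[b] <- setdiff(c("A", "C", "G", "T"), a1[b])[1]
  if (a1[b + 1] == b1[b + 1]) b1[b + 1] <- setdiff(c("A", "C", "G", "T"), a1[b + 1])[1]
  tips[["B1"]] <- paste(b1, collapse = "")
  query <- paste(c(a1[1:b], b1[(b + 1):L]), collapse = "")
  list(query = c(Q = query), refs = tips,
       taxa = c(A1 = "species_A", A2 = "species_A",
                B1 = "species_B", B2 = "species_B"),
       markers = data.frame(gene = "m1", start = 101L, end = 600L,
                            strand = "+", stringsAsFactors = FALSE),
       truth_b = b)
}
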