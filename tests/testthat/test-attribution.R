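# hand-built window_scan objects let classification and merging be tested
# against exact expectations
fake_scan <- function(d_by_ref, window = 100) {
  nw <- nrow(d_by_ref)
  structure(list(starts = seq(1L, by = window, length.out = nw),
                 ends = seq(window, by = window, length.out = nw),
                 d = d_by_ref,
                 sites = matrix(window, nw, ncol(d_by_ref),
                                dimnames = dimnames(d_by_ref)),
                 ref_ids = colnames(d_by_ref), query_id = "q",
                 window = window, step = window, policy = "pairwise"),
            class = "window_scan")
}

taxa2 <- c(V1 = "V", H1 = "H")

test_that("classify_windows applies threshold, margin and tie rules", {
  d <- rbind(c(0.004, 0.12),    # clear V
             c(0.20, 0.19),     # both above tau
             c(0.010, 0.008),   # margin 0.002 < delta
             c(0.01, 0.01))     # exact tie -> unattributed (margin 0)
  colnames(d) <- c("V1", "H1")
  cl <- classify_windows(fake_scan(d), taxa2, tau_attr = 0.05,
                         delta_margin = 0.005)
  expect_identical(cl$labels, c("V", "unattributed", "unattributed",
                                "unattributed"))
  # with no margin requirement, an exact tie goes to the lexicographically
  # first species
  cl0 <- classify_windows(fake_scan(d), taxa2, tau_attr = 0.05,
                          delta_margin = 0)
  expect_identical(cl0$labels[4], "H")
})

test_that("merge_segments builds maximal runs and absorbs short ones", {
  lab_scan <- function(labels) {
    d <- matrix(0.2, length(labels), 2, dimnames = list(NULL, c("V1", "H1")))
    d[labels == "V", "V1"] <- 0.005
    d[labels == "H", "H1"] <- 0.005
    fake_scan(d)
  }
  s1 <- lab_scan(c("V", "V", "V", "V", "H", "H", "H", "V", "V", "V"))
  m1 <- merge_segments(c("V", "V", "V", "V", "H", "H", "H", "V", "V", "V"),
                       s1, min_run = 2)
  expect_identical(m1$label, c("V", "H", "V"))
  expect_identical(m1$start[1], 1L)
  expect_identical(m1$end[3], 1000L)
  # segments tile the genome contiguously before refinement
  expect_identical(m1$start[-1], m1$end[-3] + 1L)

  m2 <- merge_segments(c("V", "V", "H", "V", "V"), lab_scan(rep("V", 5)),
                       min_run = 2)
  expect_identical(m2$label, "V")
  expect_identical(c(m2$start, m2$end), c(1L, 500L))

  m3 <- merge_segments(rep("V", 6), lab_scan(rep("V", 6)), min_run = 2)
  expect_identical(nrow(m3), 1L)
})

test_that("refine_breakpoint recovers planted boundaries exactly", {
  set.seed(31)
  pair <- plant_flank_difference(make_donor_pair(1200, 0.05), c(600, 601))
  q <- paste(c(pair$d1[1:600], pair$d2[601:1200]), collapse = "")
  aln <- build_panel_alignment(c(q = q),
                               c(L = paste(pair$d1, collapse = ""),
                                 R = paste(pair$d2, collapse = "")))
  bp <- refine_breakpoint(aln, "L", "R", c(450, 750))
  expect_identical(bp$b, 600L)
  expect_identical(bp$r, 601L)
  expect_false(bp$flagged)

  # no informative sites: midpoint fallback, flagged
  q2 <- random_dna(100)
  aln2 <- build_panel_alignment(c(q = q2), c(L = q2, R = q2))
  bp2 <- refine_breakpoint(aln2, "L", "R", c(20, 81))
  expect_true(bp2$flagged)
  expect_identical(bp2$b, 50L)
})

test_that("breakpoint recovery under query noise stays near the truth when
           informative sites flank it", {
  set.seed(77)
  n_checked <- 0L; n_ok <- 0L
  for (rep in 1:200) {
    pair <- make_donor_pair(1200, 0.05)
    b_true <- sample(400:800, 1)
    qv <- c(pair$d1[1:b_true], pair$d2[(b_true + 1):1200])
    noise <- which(runif(1200) < 0.005)
    qv[noise] <- vapply(qv[noise], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
    aln <- build_panel_alignment(c(q = paste(qv, collapse = "")),
                                 c(L = paste(pair$d1, collapse = ""),
                                   R = paste(pair$d2, collapse = "")))
    # condition on an informative site within 25 bp left of the truth that
    # the noise did not touch
    window <- max(1, b_true - 25):b_true
    informative <- pair$d1[window] != pair$d2[window] &
      !(window %in% noise)
    if (!any(informative)) next
    n_checked <- n_checked + 1L
    bp <- refine_breakpoint(aln, "L", "R", c(b_true - 150, b_true + 150))
    if (abs(bp$b - b_true) <= 25) n_ok <- n_ok + 1L
  }
  expect_gt(n_checked, 100L)
  expect_gte(n_ok / n_checked, 0.95)
})

test_that("attribution_fractions reproduces the published arithmetic", {
  seg <- segment_attribution(
    start = c(1, 14308, 15308, 16151),
    end = c(14301, 15294, 15895, 16673),
    label = c("Vespertilio sinensis", "Hypsugo alaschanicus",
              "Vespertilio sinensis", "Vespertilio sinensis"),
    genome_length = 16673)
  fr <- attribution_fractions(seg)
  expect_equal(unname(fr$fractions["Vespertilio sinensis"]), 92.4)
  expect_equal(unname(fr$fractions["Hypsugo alaschanicus"]), 5.9)

  one <- segment_attribution(1, 5000, "X", 5000)
  expect_equal(unname(attribution_fractions(one)$fractions["X"]), 100.0)

  expect_error(segment_attribution(1, 6000, "X", 5000), "exceed")
  expect_error(segment_attribution(c(1, 50), c(60, 100), c("X", "Y"), 100),
               "overlap")
})

test_that("fractions and unattributed always sum to 100 within rounding", {
  set.seed(12)
  for (i in 1:30) {
    L <- sample(5000:20000, 1)
    cuts <- sort(sample(2:(L - 1), sample(2:8, 1)))
    starts <- c(1, cuts + 1)
    ends <- c(cuts, L)
    keep <- runif(length(starts)) < 0.8   # drop some segments -> gaps
    if (!any(keep)) keep[1] <- TRUE
    seg <- segment_attribution(starts[keep], ends[keep],
                               sample(c("A", "B", "C"), sum(keep), TRUE), L)
    fr <- attribution_fractions(seg)
    expect_lte(abs(sum(fr$fractions) + fr$unattributed_pct - 100), 0.1 + 1e-9)
    expect_equal(sum(fr$fractions_raw) + fr$unattributed_raw, 100)
  }
})

test_that("diagnose is invariant to reference input order", {
  sc <- small_mosaic_scenario(seed = 5)
  cfg <- diagnose_config(bootstrap = 25, seed = 1, window = 200, step = 50)
  r1 <- diagnose(sc$query, sc$refs, sc$taxa, sc$markers, cfg)
  r2 <- diagnose(sc$query, rev(sc$refs), sc$taxa, sc$markers, cfg)
  expect_identical(r1$segments, r2$segments)
  expect_identical(r1$fractions, r2$fractions)
  expect_identical(r1$breakpoints, r2$breakpoints)
  expect_identical(r1$marker_placements, r2$marker_placements)
})

test_that("diagnose flags a two-donor mosaic and recovers its breakpoint", {
  sc <- small_mosaic_scenario(seed = 17, L = 2000, b = 1000)
  rep <- diagnose(sc$query, sc$refs, sc$taxa, sc$markers,
                  diagnose_config(bootstrap = 25, seed = 1, window = 200,
                                  step = 50))
  expect_true(rep$incongruent)
  expect_setequal(rep$donors, c("species_A", "species_B"))
  expect_true(1000 %in% rep$breakpoints)
  fr_sum <- sum(rep$fractions) + rep$unattributed_pct
  expect_lte(abs(fr_sum - 100), 0.1)
})
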