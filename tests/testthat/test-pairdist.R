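char_mat <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(rows)
  m
}

test_that("p_distance counts differing sites over comparable columns", {
  expect_equal(p_distance("ACGT", "ACGT"), list(p = 0, n_sites = 4L))
  expect_equal(p_distance("ACGT", "ACGA"), list(p = 0.25, n_sites = 4L))
  # gaps and ambiguity codes are missing data
  expect_equal(p_distance("AC-T", "ACGT"), list(p = 0, n_sites = 3L))
  expect_equal(p_distance("ACRT", "ACGT"), list(p = 0, n_sites = 3L))
  expect_error(p_distance("ACG", "ACGT"), "length")
  expect_equal(p_distance("---", "ACG")$n_sites, 0L)
  expect_true(is.na(p_distance("---", "ACG")$p))
})

test_that("complete deletion masks columns missing in any row", {
  # hand enumeration: column 3 is masked by A's gap
  m <- char_mat(A = "AC-T", B = "ACGT", C = "AAGT")
  dm <- distance_matrix(m, policy = "complete")
  expect_equal(dm$d["A", "B"], 0)
  expect_equal(dm$d["A", "C"], 1 / 3)
  expect_equal(dm$d["B", "C"], 1 / 3)
  expect_true(all(dm$sites[upper.tri(dm$sites)] == 3L))
})

test_that("distance_matrix equals per-pair p_distance calls and ape's raw model", {
  set.seed(21)
  rows <- lapply(1:5, function(i) {
    x <- strsplit(random_dna(200), "")[[1]]
    x[sample(200, 8)] <- "-"
    paste(x, collapse = "")
  })
  names(rows) <- paste0("s", 1:5)
  m <- do.call(char_mat, rows)
  dm <- distance_matrix(m, policy = "pairwise")
  for (i in 1:4) for (j in (i + 1):5) {
    pd <- p_distance(m[i, ], m[j, ])
    expect_equal(dm$d[i, j], pd$p)
    expect_equal(dm$sites[i, j], pd$n_sites)
  }
  expect_equal(dm$d, t(dm$d))

  # independent cross-check: ape::dist.dna, uncorrected, pairwise deletion
  bin <- ape::as.DNAbin(tolower(m))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  expect_equal(unname(dm$d), unname(ref), tolerance = 1e-12)

  # complete-deletion site count is one constant across all pairs
  dmc <- distance_matrix(m, policy = "complete")
  expect_length(unique(dmc$sites[upper.tri(dmc$sites)]), 1L)
  refc <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = FALSE))
  expect_equal(unname(dmc$d), unname(refc), tolerance = 1e-12)
})

test_that("p_distance is symmetric and matches the mismatch-count oracle", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(10:80, 1)
    a <- random_dna(n); b <- random_dna(n)
    pd <- p_distance(a, b)
    expect_equal(pd$p, oracle_p(a, b)$p)
    expect_equal(p_distance(b, a)$p, pd$p)
  }
})

test_that("window_scan produces spec-shaped windows and correct distances", {
  set.seed(3)
  q <- random_dna(1000)
  aln <- build_panel_alignment(c(q = q), c(r = q))
  sc <- window_scan(aln, window = 300, step = 50)
  expect_true(all(sc$d == 0))
  widths <- sc$ends - sc$starts + 1
  expect_true(all(widths[-length(widths)] == 300))
  expect_true(widths[length(widths)] >= 150)
  expect_equal(unique(diff(sc$starts)), 50)

  # window distances equal p_distance on the manually sliced sub-alignment
  r2 <- strsplit(q, "")[[1]]
  r2[sample(1000, 60)] <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  aln2 <- build_panel_alignment(c(q = q), c(r2 = paste(r2, collapse = "")))
  sc2 <- window_scan(aln2, window = 300, step = 200)
  for (k in seq_along(sc2$starts)) {
    idx <- sc2$starts[k]:sc2$ends[k]
    pd <- p_distance(aln2$mat["q", idx], aln2$mat["r2", idx])
    expect_equal(unname(sc2$d[k, "r2"]), pd$p)
    expect_equal(unname(sc2$sites[k, "r2"]), pd$n_sites)
  }

  expect_error(window_scan(aln, window = 10), "window")
  expect_error(window_scan(aln, window = 300, step = 400), "step")
  expect_warning(window_scan(build_panel_alignment(c(q = random_dna(100)),
                                                   c(r = random_dna(100))),
                             window = 300),
                 "shorter than window")
})

test_that("a two-donor mosaic separates cleanly in the scan", {
  set.seed(8)
  pair <- make_donor_pair(1000, div = 0.10)
  qa <- paste(c(pair$d1[1:500], pair$d2[501:1000]), collapse = "")
  refs <- c(refA = paste(pair$d1, collapse = ""),
            refB = paste(pair$d2, collapse = ""))
  sc <- window_scan(build_panel_alignment(c(q = qa), refs),
                    window = 100, step = 100)
  left <- sc$ends <= 500
  right <- sc$starts > 500
  expect_true(all(sc$d[left, "refA"] < sc$d[left, "refB"]))
  expect_true(all(sc$d[right, "refB"] < sc$d[right, "refA"]))
  expect_true(all(sc$d[left, "refA"] == 0))
})

test_that("scan_as_table emits one row per window and reference", {
  set.seed(4)
  q <- random_dna(500)
  aln <- build_panel_alignment(c(q = q), c(a = q, b = q))
  sc <- window_scan(aln, window = 100, step = 100)
  tab <- scan_as_table(sc)
  expect_identical(nrow(tab), length(sc$starts) * 2L)
  expect_named(tab, c("start", "end", "ref", "p", "n_sites"))
})
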