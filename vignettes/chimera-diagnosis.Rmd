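---
title: "Diagnosing chimeric mitogenomes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing chimeric mitogenomes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Public sequence archives contain complete mitochondrial genomes that are not
what their label says. Beyond simple misidentification, a submission can be a
*chimera*: a mosaic assembled — through template carry-over, PCR
contamination, or assembly/editing mistakes — from fragments of two or more
species. A chimeric mitogenome is more insidious than a misidentified one,
because every single-marker check can pass: each fragment, viewed alone,
looks like a clean sequence of *some* real species. Chimeras are only exposed
when (i) several marker genes place the query with *different*,
non-overlapping species, or (ii) the whole genome is compared directly,
position by position, against genomes of the candidate donor species.

`chimeradx` implements that two-pronged diagnosis as a reusable, tested
pipeline. Its motivating case is a published bat mitogenome (16,673 bp,
deposited as a serotine bat) that turned out to be 92.4% *Vespertilio
sinensis* (bp 1–14,301, 15,308–15,895, 16,151–16,673), 5.9% *Hypsugo
alaschanicus* (bp 14,308–15,294), with a 243 bp fragment (bp 15,908–16,150)
matching no known species. The package ships a synthetic generator that
reproduces exactly this mosaic structure with known ground truth, so the
whole pipeline is testable offline.

## The procedure

Given a query genome, a labelled reference panel (FASTA + id→species map) and
a marker table (gene, start, end, strand in query coordinates):

1. **Query-anchored alignment.** Every reference is aligned pairwise to the
   query (global Needleman–Wunsch with affine gaps; defaults match +1,
   mismatch −1, gap open −4, gap extend −1). The alignment is projected onto
   query coordinates: one column per query base, references show `-` where
   deleted, and reference insertions are recorded separately but excluded
   from query-coordinate analyses. For the near-collinear congeneric
   mitogenomes this tool targets, a query-coordinate frame carries the same
   information as a progressive multiple alignment while staying testable
   against a brute-force oracle. Inputs are assumed co-linearized (circular
   permutation is out of scope).

2. **Marker gene trees.** For each marker, the alignment columns of that
   gene give a distance matrix of uncorrected p-distances under *complete
   deletion* (every column with a gap or ambiguous base in any sequence is
   removed before any pair is compared). Neighbor-joining builds the tree;
   1,000 bootstrap column resamples give bipartition supports. The query's
   *nearest-species set* is the set of species in the smallest
   well-supported (≥ 70%) clade containing the query and at least one other
   leaf, evaluated over both orientations of every bipartition. Placements
   are **incongruent** when two markers give disjoint sets. Overlapping sets
   are deliberately not flagged: a query that consistently clusters with the
   wrong species is evidence of misidentification, not chimerism, and the
   two cannot be distinguished from placement alone. Distance trees stand in
   for the maximum-likelihood trees a full study would use; at the
   divergences that matter here (<1% within species versus ≥2.5% between)
   the query's local placement does not depend on that choice, and reports
   label the trees "distance-based".

3. **Sliding-window scan.** A window (default 300 bp, step 50 bp) slides
   along the query; in each window the p-distance from the query to every
   reference is computed under *pairwise deletion* (complete deletion inside
   a 300 bp window discards too much whenever any one reference has an
   indel). The distance to a *species* is the minimum over that species'
   references — a query should be judged against its best conspecific
   representative. Defaults localize a ~1 kb foreign segment comfortably;
   both are exposed as options.

4. **Window classification.** A window is attributed to the nearest species
   when that distance is ≤ `tau_attr` (default 0.05) *and* the runner-up
   species is at least `delta_margin` (default 0.005) further away;
   otherwise it is *unattributed*. The 5% threshold sits well above observed
   within-species matches (0.2–0.9%) and below between-species distances
   (≥2.5%) in the motivating case; "unattributed" is always relative to the
   supplied panel — no external database search is attempted, since none
   would have helped in the motivating case either.

5. **Segment merging.** Maximal runs of identically labelled windows become
   segments; runs shorter than `min_run` (default 2) windows are absorbed
   into the longer flank (ties to the left). Provisional boundaries are
   midpoints between the centres of discordant adjacent windows.

6. **Breakpoint refinement.** Between two donor segments, *informative
   sites* are columns where the two donors differ and the query matches
   exactly one. The last bp `b` of the left segment maximizes
   (left-matching sites ≤ b) + (right-matching sites > b), ties to the
   smallest `b`; the first bp `r` of the right segment is the mirror-image
   statistic with ties to the largest `r`. When `r > b + 1` the query
   matches *neither* donor in between and the gap is reported as
   unattributed rather than silently assigned — real chimeras show exactly
   such leftover gaps (e.g. bp 14,302–14,307 in the motivating case). When
   informative sites sit at both boundary flanks, `b` and `r` are exact and
   adjacent. With no informative sites at all, the provisional midpoint is
   used and flagged. Edges between a donor segment and unattributed
   sequence use a weighted change-point on query–donor agreement: agreements
   score +1, disagreements (including donor-row gaps, which are themselves
   evidence against donor identity) score −3, so a stretch counts as
   donor-like only above 75% identity. The weight matters because the
   pairwise alignment of genuinely novel sequence against a donor produces
   runs of coincidental matches (~30–50% identity); an unweighted
   change-point drifts into such runs, a 75% requirement does not, and
   genuine donor sequence (≥99% identity) is far above it.

7. **Fractions and verdict.** Per-donor fractions are summed segment
   lengths over the genome length, ×100, rounded half-up to one decimal
   (raw values are kept in the JSON report); positions in no donor segment
   count as unattributed, so fractions plus unattributed always total 100
   within rounding. The query is flagged (`incongruent = TRUE`, CLI exit
   code 2) when marker placements are disjoint *or* attribution finds two
   or more donors.

## The synthetic generator

`evolve_sequences()` simulates sequences along a guide tree under
Jukes–Cantor: along a branch of length *t* substitutions/site each site
changes with probability (3/4)(1 − e^(−4t/3)) to a uniformly chosen other
base. `make_chimera()` copies donor slices verbatim according to a
ground-truth segment table; positions in "novel" segments are resampled from
bases differing from every donor (per-site probability `novel_rate`), which
guarantees unattributability as the rate approaches 1.

`paper_mirror_scenario()` fixes the study conditions: genome length
16,673 bp; two donor-species panels (2 and 3 genomes) at ~0.5% within-species
divergence, ~10–11% between species, plus one outgroup; the exact published
segment coordinates as truth (the published table's short unlisted gaps are
generated as novel sequence, as is the 243 bp fragment); a 698 bp "COI"
marker inside the major-donor region and a 1,140 bp "cytb" marker straddling
the donor switch at its local bp 136/137. Within-species 0.5% and
between-species ~10% bracket the motivating case's observed 0.2–0.9%
(match) versus 2.5–3.0% (non-match) regimes. Two deliberate design choices
keep the ground truth exact:

* Donor genomes are simulated co-linear (no indels), so truth coordinates
  need no lift-over. (Alignment with indels is exercised separately by the
  aligner tests.)
* At the four donor-segment boundary positions (14,301/14,308 and
  15,294/15,308) the two donor species are forced to carry different bases.
  A breakpoint is only identifiable at single-nucleotide resolution if an
  informative site sits at the boundary flank; planting one there makes the
  constructed truth recoverable *exactly*, which is what the end-to-end
  checks assert. Novel segments use `novel_rate = 1` in the mirror for the
  same reason: every novel base differs from both donors, so segment edges
  are sharp.

What the generator does **not** emulate: codon structure and selection,
strand-asymmetric substitution, rate heterogeneity across sites, indel
polymorphism within species, heteroplasmy, and sequencing error. Passing
tests on the mirror therefore show that the *procedure* recovers a known
mosaic under realistic divergences — not that every real chimera presents
boundaries this clean. On real data, breakpoints between closely related
donors are identifiable only up to the nearest informative sites, and the
reported `b`/`r` bracket (rather than pinpoint) the physical junction when
those sites are sparse.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere (BED input is converted on
  read, with a message). Breakpoints are reported as the last bp of the
  left segment, so a boundary prints as the pair 136|137.
* All characters outside A/C/G/T (gaps, N, other IUPAC codes) are missing
  data for every distance computation; they are retained in the alignment.
* Species ties in window classification go to the lexicographically first
  name; donor-representative ties go to the lexicographically first
  reference id; references are sorted by id at entry — together these make
  reports invariant to input order.
* Negative NJ branch lengths are clamped to 0. Bootstrap replicates in which
  some pair has no comparable site are skipped, counted and warned about; an
  alignment with zero variable sites triggers a degeneracy warning.
* A query shorter than one window is scanned as a single full-length window
  (with a warning); the trailing window is kept when at least half a window
  long.
* Fractions are rounded half-up (so 92.35 prints as 92.4, independent of the
  platform's banker's rounding); raw values stay in the report.
* The problem sizes used by the shipped checks — a 16,673 bp mirror genome
  with a 6-genome panel for the end-to-end run, 1.2–2 kb genomes for
  property sweeps over 50–200 seeds, bootstrap 1,000 for the mirror and
  20–25 for the sweeps — were chosen so the full suite exercises every path
  at study-scale divergences while remaining quick on a laptop.

## Known limitations

* Attribution is only as good as the panel: a donor species absent from the
  panel yields unattributed segments, not an identification.
* The pipeline assumes a curated panel of a handful of candidate species;
  it is not designed to resolve chimeras of many (>~5) donors.
* Model-corrected distances (JC, K2P) are intentionally not offered for the
  scan — the diagnosis rests on uncorrected p-distances, and at the
  relevant divergences the correction is negligible relative to the
  attribution threshold.
* Placement incongruence needs at least two markers; with one marker the
  verdict rests on the scan alone.
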