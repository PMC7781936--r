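Package: chimeradx
Title: Chimera Diagnosis for Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects chimeric (mosaic) mitochondrial genome submissions by
    combining two complementary signals: incongruent placement of the query
    across marker-gene trees (e.g. COI versus cytochrome b), and direct
    sliding-window comparison of the query against a labelled reference
    panel using uncorrected p-distances. Mosaic segments are attributed to
    donor species, breakpoints are refined to nucleotide resolution from
    informative sites, segments matching no panel species are flagged as
    unattributed, and per-donor genome fractions are reported. Includes a
    synthetic-data generator (Jukes-Cantor evolution along a guide tree,
    mosaic query construction with known breakpoints) so the whole pipeline
    is testable without external downloads, plus a small command-line
    interface for screening candidate submissions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
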