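Package: ecrtools
Title: Comparative-Genomics Detection of Evolutionarily Conserved Regions in
    Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for locating evolutionarily conserved regions (ECRs)
    in upstream promoter sequences across a mammalian clade: sliding-window
    percent-identity profiling of pairwise alignments with conserved-block
    (ECR/CoreECR) calling, chunked cross-species homology search tolerant of
    genomic insertions and deletions, progressive multiple alignment of
    full-length ECRs with minimal-shared-ECR extraction and case-encoded
    consensus construction, and position-weight-matrix scanning with a
    cross-species flank-conservation filter for transcription-factor binding
    sites. A bundled promoter-evolution simulator generates clades with known
    truth (constrained elements, planted motifs) so every stage is testable
    without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
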