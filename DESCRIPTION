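Package: foxscan
Title: Ortholog Classification for Fox Transcription-Factor Subfamilies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale implementation of the classic two-pronged
    ortholog-identification procedure used to survey genomes for members of a
    transcription-factor subfamily such as FoxJ1: similarity search with an
    E-value filter, excision of the conserved forkhead (FKH) domain, progressive
    multiple alignment, neighbor-joining phylogeny with bootstrap bipartition
    support, reverse best-hit subfamily assignment, and rule-based ortholog
    calling (definite / candidate / not detected). Includes a synthetic
    gene-family generator with known trees and labels so the whole pipeline is
    testable without downloads, and a bundled evidence table from a published
    eukaryote-wide FoxJ1 survey for exercising the decision rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ape,
    phangorn,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
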