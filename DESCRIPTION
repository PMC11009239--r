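Package: soloLTR
Title: Identification and Evolutionary Analysis of Solitary LTRs of Endogenous Retroviruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering solitary long terminal repeats (solo-LTRs)
    left behind by unequal homologous recombination between the paired LTRs of
    endogenous retroviruses (ERVs). Builds a non-redundant LTR library from two
    candidate annotation sources, scans genome assemblies for LTR matches with a
    seed-and-extend aligner, partitions hits into intact LTR pairs and solo-LTRs
    by reciprocal-best-hit matching, verifies target-site duplications, and
    computes per-genome solo-LTR formation statistics. Cross-species sharing of
    solo-LTRs is traced from whole-genome-alignment blocks and attributed to
    ancestral nodes of a species tree, and insertion polymorphism is called from
    per-individual coverage tracks. A synthetic-genome simulator with exact
    ground truth (planted ERVs, solo-LTRs, populations and multi-species
    alignments) supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
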