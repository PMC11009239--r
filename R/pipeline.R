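#' Run the full solo-LTR discovery pipeline on one genome
#'
#' Chains the annotation and classification stages with their standard
#' thresholds: intersect the two candidate annotation sets (100-1000 bp),
#' extract and (optionally) family-label the candidate sequences, cluster
#' them into a non-redundant library at 95% identity, scan the genome
#' (65% identity / 80% query coverage), resolve overlapping hits, drop hits
#' on scaffolds under 20 kb, and partition the remainder into LTR pairs and
#' solo-LTRs by reciprocal best hit (20 kb window, 85% identity).
#'
#' @param genome genome sequences (named character vector, `DNAStringSet` or
#'   `sim_genome`).
#' @param cand_a,cand_b the two candidate LTR interval sets.
#' @param reference optional classified reference LTR set for
#'   [assign_families()]; without it all families are `"unknown"`.
#' @param min_len,max_len candidate length bounds (bp).
#' @param clustering_identity library redundancy threshold (proportion).
#' @param min_identity,min_qcov scan thresholds (percent).
#' @param min_scaffold minimum scaffold length (bp).
#' @param window,min_pair_identity pairing thresholds (bp, percent).
#' @return list with `library`, `hits` (clustered + filtered), `partition`
#'   (an `ltr_partition`) and `stats` (formation statistics).
#' @export
solo_ltr_pipeline <- function(genome, cand_a, cand_b, reference = NULL,
                              min_len = 100, max_len = 1000,
                              clustering_identity = 0.95,
                              min_identity = 65, min_qcov = 80,
                              min_scaffold = 20000,
                              window = 20000, min_pair_identity = 85) {
  genome <- .as_character_genome(genome)
  ivs <- intersect_candidates(cand_a, cand_b, min_len, max_len)
  seqs <- extract_sequences(genome, ivs)
  if (!is.null(reference)) seqs <- assign_families(seqs, reference)
  lib <- build_library(seqs, clustering_identity, min_len, max_len)
  hits <- scan_genome(genome, lib, min_identity, min_qcov)
  hits <- cluster_hits(hits)
  hits <- filter_scaffolds(hits, setNames(nchar(genome), names(genome)), min_scaffold)
  partition <- pair_ltrs(hits, genome, window, min_pair_identity)
  list(library = lib, hits = hits, partition = partition,
       stats = compute_formation_stats(partition, genome))
}

#' Formation-ratio sensitivity sweep over pairing thresholds
#'
#' Re-runs the pairing stage over a grid of identity thresholds and pairing
#' windows and reports the resulting formation ratio, mirroring the usual
#' robustness check on the 85% / 20 kb defaults.
#'
#' @param hits clustered, scaffold-filtered hit table.
#' @param genome genome sequences.
#' @param identities percent identity thresholds to sweep.
#' @param windows pairing windows (bp) to sweep.
#' @return data.frame: `min_pair_identity`, `window`, `pair_count`,
#'   `solo_count`, `formation_ratio`.
#' @export
pairing_threshold_sweep <- function(hits, genome,
                                    identities = c(75, 80, 85, 90, 95),
                                    windows = 20000) {
  out <- NULL
  for (w in windows) {
    for (idv in identities) {
      part <- pair_ltrs(hits, genome, window = w, min_pair_identity = idv)
      fs <- compute_formation_stats(part, genome, per_family = FALSE)
      out <- rbind(out, data.frame(
        min_pair_identity = idv, window = w,
        pair_count = nrow(part$pairs), solo_count = nrow(part$solos),
        formation_ratio = fs$formation_ratio[1]))
    }
  }
  out
}
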