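# Pairing of LTR hits into intact proviruses vs solo-LTRs, TSD verification,
# and per-genome solo-LTR formation statistics.

# Reciprocal-best-hit extraction over a candidate edge table.
# `edges`: data.frame with columns i, j (hit indices, i < j), identity, gap,
# left_start. Semantics: repeatedly (a) compute, for every remaining hit, its
# best partner = max identity (>= threshold), ties -> smallest gap, then
# smallest partner start; (b) collect mutual-best pairs; (c) extract the one
# with highest identity (ties -> smallest gap, then smallest left start) and
# remove both hits; stop when no mutual-best pair remains. Returns a matrix
# with columns i, j of extracted pairs.
.rbh_extract <- function(edges, n_hits, starts) {
  alive <- rep(TRUE, n_hits)
  out <- NULL
  if (is.null(edges) || nrow(edges) == 0) return(matrix(integer(0), ncol = 2))
  repeat {
    e <- edges[alive[edges$i] & alive[edges$j], , drop = FALSE]
    if (nrow(e) == 0) break
    best <- rep(NA_integer_, n_hits)
    for (h in which(alive)) {
      cand_j <- c(e$j[e$i == h], e$i[e$j == h])
      if (!length(cand_j)) next
      idv <- c(e$identity[e$i == h], e$identity[e$j == h])
      gap <- c(e$gap[e$i == h], e$gap[e$j == h])
      ord <- order(-idv, gap, starts[cand_j])
      best[h] <- cand_j[ord[1]]
    }
    mut_i <- which(!is.na(best) & best[best] == seq_len(n_hits) & seq_len(n_hits) < best)
    if (!length(mut_i)) break
    mut_j <- best[mut_i]
    key <- match(paste(pmin(mut_i, mut_j), pmax(mut_i, mut_j)), paste(e$i, e$j))
    idv <- e$identity[key]; gap <- e$gap[key]
    pick <- order(-idv, gap, pmin(starts[mut_i], starts[mut_j]))[1]
    out <- rbind(out, c(mut_i[pick], mut_j[pick]))
    alive[c(mut_i[pick], mut_j[pick])] <- FALSE
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

#' Partition LTR hits into LTR pairs and solo-LTRs by reciprocal best hit
#'
#' Candidate partners of a hit are hits on the same scaffold and strand whose
#' inner gap (distance between facing interval boundaries) is within `window`.
#' Partner affinity is the percent identity of the two hit sequences under
#' global alignment; pairs are mutual-best matches at `min_pair_identity` or
#' above, extracted greedily in descending identity with recomputation after
#' each extraction (ties: smaller inner gap, then smaller start coordinate).
#' Everything left unpaired is a solo-LTR. The two LTRs of an intact provirus
#' are direct repeats, hence the same-strand requirement; opposite-strand
#' near-identical neighbours are ignored as partners.
#'
#' @param hits non-overlapping hit table (run [cluster_hits()] and
#'   [filter_scaffolds()] first).
#' @param genome the genome the hits were called on.
#' @param window maximum inner gap in bp (default 20000).
#' @param min_pair_identity minimum percent identity between the two LTR
#'   copies of a pair (default 85).
#' @param distance_mode `"gap"` measures facing-boundary distance
#'   (right.start - left.end); `"span"` measures outer span
#'   (right.end - left.start).
#' @return class `ltr_partition`: list with `pairs` (one row per pair:
#'   left/right hit coordinates and ids, `inner_gap`, `pair_identity`),
#'   `solos` (hit rows left unpaired) and the thresholds used.
#' @export
pair_ltrs <- function(hits, genome, window = 20000, min_pair_identity = 85,
                      distance_mode = c("gap", "span")) {
  distance_mode <- match.arg(distance_mode)
  hits <- .check_hits(hits)
  genome <- .as_character_genome(genome)
  # Precondition: pairwise non-overlapping (the output contract of cluster_hits).
  for (s in unique(hits$scaffold)) {
    h <- hits[hits$scaffold == s, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    if (nrow(h) > 1 && any(h$start[-1] < h$end[-nrow(h)])) {
      .stopf("hits overlap on scaffold %s; run cluster_hits() before pairing", s)
    }
  }
  n <- nrow(hits)
  if (n == 0) {
    return(structure(list(pairs = .empty_pairs(), solos = hits,
                          window = window, min_pair_identity = min_pair_identity),
                     class = "ltr_partition"))
  }
  seqs <- vapply(seq_len(n), function(i) {
    subseq0(genome[[hits$scaffold[i]]], hits$start[i], hits$end[i])
  }, "")

  edges <- NULL
  ord <- order(hits$scaffold, hits$start)
  for (a in seq_along(ord)) {
    i <- ord[a]
    b <- a + 1L
    while (b <= n) {
      j <- ord[b]
      if (hits$scaffold[j] != hits$scaffold[i]) break
      gap <- if (distance_mode == "gap") hits$start[j] - hits$end[i]
             else hits$end[j] - hits$start[i]
      if (hits$start[j] - hits$end[i] > window) break  # sorted: no later j is closer
      if (hits$strand[j] == hits$strand[i] && gap <= window && gap >= 0) {
        idv <- global_identity(seqs[i], seqs[j])
        if (idv >= min_pair_identity) {
          edges <- rbind(edges, data.frame(i = min(i, j), j = max(i, j),
                                           identity = idv, gap = gap))
        }
      }
      b <- b + 1L
    }
  }
  pm <- .rbh_extract(edges, n, hits$start)
  paired <- sort(unique(as.vector(pm)))
  pairs <- .empty_pairs()
  if (nrow(pm)) {
    for (k in seq_len(nrow(pm))) {
      i <- pm[k, 1]; j <- pm[k, 2]
      left <- if (hits$start[i] <= hits$start[j]) i else j
      right <- if (left == i) j else i
      e <- which((edges$i == min(i, j)) & (edges$j == max(i, j)))
      pairs <- rbind(pairs, data.frame(
        scaffold = hits$scaffold[left], strand = hits$strand[left],
        left_id = hits$hit_id[left], right_id = hits$hit_id[right],
        left_start = hits$start[left], left_end = hits$end[left],
        right_start = hits$start[right], right_end = hits$end[right],
        family = hits$family[left],
        inner_gap = hits$start[right] - hits$end[left],
        pair_identity = edges$identity[e][1],
        stringsAsFactors = FALSE))
    }
    pairs <- pairs[order(pairs$scaffold, pairs$left_start), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  solos <- hits[setdiff(seq_len(n), paired), , drop = FALSE]
  solos <- solos[order(solos$scaffold, solos$start), , drop = FALSE]
  rownames(solos) <- NULL
  structure(list(pairs = pairs, solos = solos, window = window,
                 min_pair_identity = min_pair_identity),
            class = "ltr_partition")
}

.empty_pairs <- function() {
  data.frame(scaffold = character(0), strand = character(0),
             left_id = character(0), right_id = character(0),
             left_start = integer(0), left_end = integer(0),
             right_start = integer(0), right_end = integer(0),
             family = character(0), inner_gap = integer(0),
             pair_identity = numeric(0), stringsAsFactors = FALSE)
}

#' Verify the target-site duplication of an element
#'
#' Integration duplicates 4-6 bp of host sequence on both sides of the
#' element; a solo-LTR inherits both copies. The check extracts `flank_length`
#' bp immediately outside each element boundary (for an LTR pair: upstream of
#' the left LTR and downstream of the right LTR) and passes iff some motif of
#' length `min_motif`..`max_motif` occurs *exactly* in both flanks. The
#' longest such motif is reported, leftmost occurrence (in the left flank,
#' then the right) on ties. Offsets measure the distance in bp between the
#' motif and the element boundary (0 = immediately adjacent).
#'
#' @param genome genome sequences.
#' @param scaffold,start,end element interval (0-based half-open; for a pair
#'   use the left LTR start and right LTR end).
#' @param flank_length flank window in bp, one of 10, 15, 20.
#' @param min_motif,max_motif motif length bounds (defaults 4 and 6).
#' @return one-row data.frame: `pass`, `motif`, `motif_length`, `left_offset`,
#'   `right_offset`, `flank_length`, `reason` (`"edge"` when the element is
#'   too close to a scaffold end to test).
#' @export
verify_tsd <- function(genome, scaffold, start, end, flank_length = 10,
                       min_motif = 4, max_motif = 6) {
  genome <- .as_character_genome(genome)
  if (!flank_length %in% c(10, 15, 20)) .stopf("flank_length must be 10, 15 or 20")
  sq <- genome[[scaffold]]
  if (is.null(sq) || is.na(sq)) .stopf("unknown scaffold '%s'", scaffold)
  fail <- function(reason) data.frame(
    pass = FALSE, motif = NA_character_, motif_length = NA_integer_,
    left_offset = NA_integer_, right_offset = NA_integer_,
    flank_length = flank_length, reason = reason, stringsAsFactors = FALSE)
  if (start < flank_length || end + flank_length > nchar(sq)) return(fail("edge"))
  left <- subseq0(sq, start - flank_length, start)
  right <- subseq0(sq, end, end + flank_length)
  tsd_match(left, right, flank_length, min_motif, max_motif)
}

# Core TSD motif search on two explicit flank strings. Exposed separately so
# empirical nulls (shuffled flanks) can reuse it.
#' @rdname verify_tsd
#' @param left_flank,right_flank flank sequences (left flank reads toward the
#'   element; its right end touches the element boundary).
#' @export
tsd_match <- function(left_flank, right_flank, flank_length = nchar(left_flank),
                      min_motif = 4, max_motif = 6) {
  fl <- nchar(left_flank)
  for (len in seq(min(max_motif, fl), min_motif)) {
    if (len > nchar(right_flank)) next
    lstarts <- seq_len(fl - len + 1L)
    lsubs <- substring(left_flank, lstarts, lstarts + len - 1L)
    for (k in seq_along(lsubs)) {
      rpos <- regexpr(lsubs[k], right_flank, fixed = TRUE)
      if (rpos > 0) {
        return(data.frame(
          pass = TRUE, motif = lsubs[k], motif_length = len,
          left_offset = fl - (lstarts[k] + len - 1L),
          right_offset = as.integer(rpos) - 1L,
          flank_length = flank_length, reason = NA_character_,
          stringsAsFactors = FALSE))
      }
    }
  }
  data.frame(pass = FALSE, motif = NA_character_, motif_length = NA_integer_,
             left_offset = NA_integer_, right_offset = NA_integer_,
             flank_length = flank_length, reason = "no_motif",
             stringsAsFactors = FALSE)
}

#' TSD reports for every element of a partition
#'
#' @param partition an [pair_ltrs()] result.
#' @param genome genome sequences.
#' @inheritParams verify_tsd
#' @return data.frame with one row per element (`element` = hit id for solos,
#'   `left_id+right_id` for pairs, plus a `type` column) and the
#'   [verify_tsd()] columns.
#' @export
verify_tsds <- function(partition, genome, flank_length = 10,
                        min_motif = 4, max_motif = 6) {
  stopifnot(inherits(partition, "ltr_partition"))
  out <- NULL
  p <- partition$pairs
  for (i in seq_len(nrow(p))) {
    rep_i <- verify_tsd(genome, p$scaffold[i], p$left_start[i], p$right_end[i],
                        flank_length, min_motif, max_motif)
    out <- rbind(out, cbind(element = paste(p$left_id[i], p$right_id[i], sep = "+"),
                            type = "pair", rep_i, stringsAsFactors = FALSE))
  }
  s <- partition$solos
  for (i in seq_len(nrow(s))) {
    rep_i <- verify_tsd(genome, s$scaffold[i], s$start[i], s$end[i],
                        flank_length, min_motif, max_motif)
    out <- rbind(out, cbind(element = s$hit_id[i], type = "solo", rep_i,
                            stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- cbind(element = character(0), type = character(0),
                 verify_tsd(setNames("A", "x"), "x", 0, 0)[0, ])
  }
  rownames(out) <- NULL
  out
}

#' Per-genome solo-LTR formation statistics
#'
#' `formation_ratio` = solo-LTR bp / total LTR bp is the frequency with which
#' proviruses have been reduced to solo-LTRs; `proportion` = solo-LTR bp /
#' genome size measures the genomic footprint of solo-LTRs. Reported per
#' family and in a `total` row.
#'
#' @param partition an [pair_ltrs()] result.
#' @param genome genome sequences (for genome size).
#' @param per_family also emit one row per ERV family (default TRUE).
#' @return data.frame with columns `family`, `genome_size`, `total_ltr_bp`,
#'   `solo_bp`, `paired_bp`, `solo_count`, `pair_count`, `proportion`,
#'   `formation_ratio`. With zero LTR bp the ratio is NaN (with a warning).
#' @export
compute_formation_stats <- function(partition, genome, per_family = TRUE) {
  stopifnot(inherits(partition, "ltr_partition"))
  genome <- .as_character_genome(genome)
  gsize <- sum(nchar(genome))
  solos <- partition$solos
  pairs <- partition$pairs
  one <- function(fam) {
    s <- if (is.null(fam)) solos else solos[solos$family == fam, , drop = FALSE]
    p <- if (is.null(fam)) pairs else pairs[pairs$family == fam, , drop = FALSE]
    solo_bp <- sum(s$end - s$start)
    paired_bp <- sum(p$left_end - p$left_start) + sum(p$right_end - p$right_start)
    total <- solo_bp + paired_bp
    ratio <- if (total == 0) NaN else solo_bp / total
    data.frame(family = if (is.null(fam)) "total" else fam,
               genome_size = gsize, total_ltr_bp = total,
               solo_bp = solo_bp, paired_bp = paired_bp,
               solo_count = nrow(s), pair_count = nrow(p),
               proportion = solo_bp / gsize, formation_ratio = ratio,
               stringsAsFactors = FALSE)
  }
  out <- one(NULL)
  if (per_family) {
    for (fam in sort(unique(c(solos$family, pairs$family)))) out <- rbind(out, one(fam))
  }
  if (any(is.nan(out$formation_ratio))) {
    .warnf("zero total LTR bp in at least one stratum: formation_ratio is NaN there")
  }
  rownames(out) <- NULL
  out
}
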