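#' Intersect two candidate LTR interval sets
#'
#' The LTR library is seeded from regions called by two independent annotation
#' sources; only their pairwise intersections within a plausible LTR length
#' range are kept. Intervals are 0-based half-open data.frames with columns
#' `scaffold`, `start`, `end`.
#'
#' @param set_a,set_b candidate interval data.frames.
#' @param min_len,max_len retained intersection length bounds in bp
#'   (defaults 100 and 1000).
#' @return data.frame of intersection intervals sorted by (scaffold, start).
#' @export
intersect_candidates <- function(set_a, set_b, min_len = 100, max_len = 1000) {
  .check_intervals(set_a, "candidate set A")
  .check_intervals(set_b, "candidate set B")
  out <- NULL
  for (s in intersect(unique(set_a$scaffold), unique(set_b$scaffold))) {
    a <- set_a[set_a$scaffold == s, , drop = FALSE]
    b <- set_b[set_b$scaffold == s, , drop = FALSE]
    ra <- IRanges::IRanges(a$start + 1L, a$end)
    rb <- IRanges::IRanges(b$start + 1L, b$end)
    ov <- IRanges::findOverlaps(ra, rb)
    if (!length(ov)) next
    qs <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    st <- pmax(a$start[qs], b$start[sh])
    en <- pmin(a$end[qs], b$end[sh])
    keep <- (en - st) >= min_len & (en - st) <= max_len
    if (any(keep)) {
      out <- rbind(out, data.frame(scaffold = s, start = st[keep], end = en[keep],
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(scaffold = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  }
  out <- unique(.sort_intervals(out))
  rownames(out) <- NULL
  out
}

#' Extract interval sequences for library building
#'
#' @param genome genome sequences.
#' @param intervals interval data.frame (`scaffold`/`start`/`end`, 0-based
#'   half-open), e.g. from [intersect_candidates()].
#' @param prefix id prefix for the extracted entries.
#' @return data.frame `id`/`family`/`sequence` (family `"unknown"`; see
#'   [assign_families()]).
#' @export
extract_sequences <- function(genome, intervals, prefix = "cand") {
  genome <- .as_character_genome(genome)
  .check_intervals(intervals, "interval set")
  seqs <- vapply(seq_len(nrow(intervals)), function(i) {
    sq <- genome[[intervals$scaffold[i]]]
    if (is.null(sq) || is.na(sq)) .stopf("unknown scaffold '%s'", intervals$scaffold[i])
    subseq0(sq, intervals$start[i], intervals$end[i])
  }, "")
  data.frame(id = sprintf("%s_%03d", prefix, seq_len(nrow(intervals))),
             family = "unknown", sequence = seqs, stringsAsFactors = FALSE)
}

#' Assign ERV family labels by best identity to reference family sequences
#'
#' Plays the role of classifying library entries against a curated repeat
#' reference: each sequence receives the family of the reference entry with
#' the highest global-alignment identity (at or above `min_identity`;
#' `"unknown"` below it).
#'
#' @param sequences data.frame with a `sequence` column.
#' @param reference data.frame `id`/`family`/`sequence` of classified
#'   reference LTRs.
#' @param min_identity minimum percent identity to accept a label
#'   (default 60).
#' @return `sequences` with its `family` column replaced.
#' @export
assign_families <- function(sequences, reference, min_identity = 60) {
  if (!nrow(reference)) .stopf("reference set is empty")
  fam <- vapply(sequences$sequence, function(sq) {
    ids <- vapply(seq_len(nrow(reference)), function(j) {
      max(global_identity(sq, reference$sequence[j]),
          global_identity(revcomp(sq), reference$sequence[j]))
    }, 1)
    if (max(ids) >= min_identity) reference$family[which.max(ids)] else "unknown"
  }, "", USE.NAMES = FALSE)
  sequences$family <- fam
  sequences
}

#' Build a non-redundant LTR library by greedy identity clustering
#'
#' Sequences are sorted longest-first and a sequence is retained iff its
#' global-alignment identity to every already-retained representative is below
#' `identity` (the shorter sequence aligned end-to-end against the longer;
#' identity = matches / alignment columns). This mirrors the conventional
#' 95%-similarity redundancy-removal step used to build repeat libraries.
#'
#' @param sequences data.frame with columns `id`, `family`, `sequence`.
#' @param identity clustering identity threshold, proportion (default 0.95).
#' @param min_len,max_len admissible sequence length range; out-of-range
#'   sequences are dropped with a message.
#' @return class `ltr_library`: data.frame `id`/`family`/`sequence` of
#'   retained representatives, with the threshold in
#'   `attr(, "clustering_identity")`.
#' @export
build_library <- function(sequences, identity = 0.95, min_len = 100, max_len = 1000) {
  if (!all(c("id", "family", "sequence") %in% names(sequences))) {
    .stopf("sequences must have columns id/family/sequence")
  }
  if (nrow(sequences) == 0) {
    .warnf("empty input: returning an empty library")
    return(structure(sequences, clustering_identity = identity, class = c("ltr_library", "data.frame")))
  }
  len <- nchar(sequences$sequence)
  drop <- len < min_len | len > max_len
  if (any(drop)) {
    message(sprintf("build_library: rejected %d sequence(s) outside [%d, %d] bp",
                    sum(drop), min_len, max_len))
    sequences <- sequences[!drop, , drop = FALSE]
  }
  if (nrow(sequences) == 0) {
    .warnf("no admissible sequences: returning an empty library")
    return(structure(sequences, clustering_identity = identity, class = c("ltr_library", "data.frame")))
  }
  sequences <- sequences[order(-nchar(sequences$sequence), sequences$id), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(sequences))) {
    redundant <- FALSE
    for (j in kept) {
      idv <- global_identity(sequences$sequence[i], sequences$sequence[j]) / 100
      if (idv >= identity) { redundant <- TRUE; break }
    }
    if (!redundant) kept <- c(kept, i)
  }
  out <- sequences[kept, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, clustering_identity = identity, class = c("ltr_library", "data.frame"))
}

# Combined seed dictionary over every query strand: one PDict of all distinct
# k-mers plus, per k-mer, the (query, strand, query offset) tuples it occurs
# in. Matching once per scaffold replaces per-query dictionary scans.
.seed_dict_all <- function(queries, seed_length) {
  qidx <- integer(0); strand <- character(0); qpos <- integer(0); kmer <- character(0)
  for (q in seq_along(queries)) {
    for (st in c("+", "-")) {
      qs <- if (st == "+") queries[q] else revcomp(queries[q])
      qlen <- nchar(qs)
      if (qlen < seed_length) next
      starts <- seq_len(qlen - seed_length + 1L)
      km <- substring(qs, starts, starts + seed_length - 1L)
      keep <- !duplicated(km)
      qidx <- c(qidx, rep(q, sum(keep)))
      strand <- c(strand, rep(st, sum(keep)))
      qpos <- c(qpos, starts[keep])
      kmer <- c(kmer, km[keep])
    }
  }
  if (!length(kmer)) return(NULL)
  uk <- unique(kmer)
  list(pd = Biostrings::PDict(Biostrings::DNAStringSet(uk)),
       map = split(seq_along(kmer), match(kmer, uk)),
       qidx = qidx, strand = strand, qpos = qpos, n_unique = length(uk))
}

# Candidate window anchors per (query, strand) on one scaffold: seed matches
# clustered by alignment diagonal (projected 0-based subject start of the
# query). Returns a data.frame qidx/strand/anchor.
.seed_windows_all <- function(dict, subject_dna, band = 25L) {
  empty <- data.frame(qidx = integer(0), strand = character(0), anchor = integer(0))
  if (is.null(dict)) return(empty)
  m <- Biostrings::matchPDict(dict$pd, subject_dna)
  nh <- S4Vectors::elementNROWS(m)
  if (!sum(nh)) return(empty)
  spos_u <- unlist(lapply(which(nh > 0), function(k) IRanges::start(m[[k]])), use.names = FALSE)
  rows_u <- unlist(lapply(which(nh > 0), function(k) rep(list(dict$map[[k]]), nh[k])),
                   recursive = FALSE)
  # expand: one record per (k-mer occurrence in subject) x (tuple using that k-mer)
  reps <- lengths(rows_u)
  rows <- unlist(rows_u, use.names = FALSE)
  spos <- rep(spos_u, reps)
  df <- data.frame(qidx = dict$qidx[rows], strand = dict$strand[rows],
                   diag = spos - dict$qpos[rows], stringsAsFactors = FALSE)
  out <- NULL
  key <- paste(df$qidx, df$strand)
  for (sub in split(df, key)) {
    d <- sort(unique(sub$diag))
    grp <- cumsum(c(1L, diff(d) > band))
    anchors <- vapply(split(d, grp), function(x) as.integer(round(stats::median(x))), 1L)
    out <- rbind(out, data.frame(qidx = sub$qidx[1], strand = sub$strand[1],
                                 anchor = anchors, stringsAsFactors = FALSE))
  }
  out %||% empty
}

#' Scan a genome for LTR library matches (seed-and-extend)
#'
#' For each library entry and each scaffold, exact k-mer seeds (length
#' `seed_length`, both strands) are clustered by alignment diagonal into
#' candidate windows, and each window is aligned locally against the query
#' under the package scoring scheme. A hit is reported iff its identity is at
#' least `min_identity` percent and the aligned query span covers at least
#' `min_qcov` percent of the query. Overlapping hits are *not* resolved here;
#' run [cluster_hits()] next.
#'
#' @param genome named character vector / `DNAStringSet` / `sim_genome`.
#' @param library an [build_library()] result, or any data.frame with
#'   `id`/`family`/`sequence`.
#' @param min_identity minimum percent identity (default 65).
#' @param min_qcov minimum percent query coverage (default 80).
#' @param seed_length exact seed length in bp (default 11).
#' @return hit data.frame: `hit_id`, `scaffold`, `start`, `end` (0-based
#'   half-open), `strand`, `library_id`, `family`, `identity`,
#'   `query_coverage`, `score`.
#' @export
scan_genome <- function(genome, library, min_identity = 65, min_qcov = 80,
                        seed_length = 11) {
  genome <- .as_character_genome(genome)
  if (!length(genome) || all(!nzchar(genome))) .stopf("genome is empty")
  if (nrow(library) == 0) .stopf("library is empty")
  hits <- NULL
  pad <- 20L
  dict <- .seed_dict_all(library$sequence, seed_length)
  for (s in names(genome)) {
    subject_chr <- genome[[s]]
    slen <- nchar(subject_chr)
    if (slen < seed_length) next
    windows <- .seed_windows_all(dict, Biostrings::DNAString(subject_chr))
    for (k in seq_len(nrow(windows))) {
      q <- windows$qidx[k]; strand <- windows$strand[k]; a <- windows$anchor[k]
      qseq <- if (strand == "+") library$sequence[q] else revcomp(library$sequence[q])
      qlen <- nchar(qseq)
      max_span <- as.integer(floor(1.5 * qlen))
      w0 <- max(0L, a - pad)
      w1 <- min(slen, a + qlen + pad)
      if (w1 - w0 < seed_length) next
      window <- substr(subject_chr, w0 + 1L, w1)
      al <- align_pair(qseq, window, "local")
      qcov <- (al$qend - al$qstart + 1L) / qlen * 100
      if (al$identity >= min_identity && qcov >= min_qcov) {
        hit_start <- w0 + al$sstart - 1L
        hit_end <- w0 + al$send
        if (hit_end - hit_start > max_span) next
        hits <- rbind(hits, data.frame(
          scaffold = s, start = hit_start, end = hit_end, strand = strand,
          library_id = library$id[q], family = library$family[q],
          identity = al$identity, query_coverage = qcov, score = al$score,
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(hits)) return(.empty_hits())
  hits <- unique(hits)
  hits <- hits[order(hits$scaffold, hits$start, hits$end, hits$strand,
                     hits$library_id), , drop = FALSE]
  hits$hit_id <- sprintf("hit_%05d", seq_len(nrow(hits)))
  rownames(hits) <- NULL
  hits[, c("hit_id", setdiff(names(hits), "hit_id"))]
}

#' Collapse overlapping hits, keeping the best per overlap cluster
#'
#' Hits on one scaffold are grouped by single-linkage interval overlap
#' (>= 1 bp, strand-agnostic); within each cluster exactly one hit is
#' retained: highest score, ties broken by higher identity, then by lower
#' start coordinate. The output is therefore an antichain under overlap.
#'
#' @param hits a hit data.frame as produced by [scan_genome()].
#' @return the retained hits, sorted by (scaffold, start), hit ids renumbered.
#' @export
cluster_hits <- function(hits) {
  hits <- .check_hits(hits)
  if (nrow(hits) == 0) return(.empty_hits())
  keep <- NULL
  for (s in unique(hits$scaffold)) {
    h <- hits[hits$scaffold == s, , drop = FALSE]
    r <- IRanges::IRanges(h$start + 1L, h$end)
    comp <- IRanges::reduce(r)
    grp <- S4Vectors::subjectHits(IRanges::findOverlaps(r, comp))
    for (g in unique(grp)) {
      cand <- h[grp == g, , drop = FALSE]
      cand <- cand[order(-cand$score, -cand$identity, cand$start), , drop = FALSE]
      keep <- rbind(keep, cand[1, , drop = FALSE])
    }
  }
  keep <- keep[order(keep$scaffold, keep$start), , drop = FALSE]
  keep$hit_id <- sprintf("hit_%05d", seq_len(nrow(keep)))
  rownames(keep) <- NULL
  keep
}

#' Drop hits on short scaffolds
#'
#' Short scaffolds are unreliable for LTR pairing (a partner within the
#' pairing window may simply be missing from the assembly), so hits on
#' scaffolds below `min_len` are removed.
#'
#' @param hits hit data.frame.
#' @param scaffold_lengths named numeric vector of scaffold lengths, or a
#'   genome object from which lengths are taken.
#' @param min_len minimum scaffold length in bp (default 20000).
#' @return the retained hits.
#' @export
filter_scaffolds <- function(hits, scaffold_lengths, min_len = 20000) {
  hits <- .check_hits(hits)
  if (!is.numeric(scaffold_lengths)) {
    g <- .as_character_genome(scaffold_lengths)
    scaffold_lengths <- setNames(nchar(g), names(g))
  }
  if (nrow(hits) == 0) return(hits)
  unknown <- setdiff(unique(hits$scaffold), names(scaffold_lengths))
  if (length(unknown)) {
    .stopf("hits reference scaffolds with unknown length: %s",
           paste(unknown, collapse = ", "))
  }
  short <- scaffold_lengths[hits$scaffold] < min_len
  if (any(short)) {
    message(sprintf("filter_scaffolds: removed %d hit(s) on scaffolds < %d bp",
                    sum(short), as.integer(min_len)))
  }
  out <- hits[!short, , drop = FALSE]
  rownames(out) <- NULL
  out
}
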