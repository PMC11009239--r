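# Shared fixtures: everything is generated in code under fixed seeds.

# A small, quick simulation for unit tests.
small_sim <- function(seed = 11, n_full = 6, n_solo = 6, divergence = 0,
                      genome_length = 120000, n_scaffolds = 2, ...) {
  cfg <- sim_config(genome_length = genome_length, n_scaffolds = n_scaffolds,
                    ltr_length = 200, internal_length = 1000,
                    n_full_erv = n_full, n_solo = n_solo,
                    divergence = divergence, seed = seed, ...)
  simulate_genome(cfg)
}

# Full discovery run on a simulated genome with the standard thresholds.
run_sim_pipeline <- function(sim, cand_seed = 1, ...) {
  cands <- candidate_sets(sim, seed = cand_seed)
  solo_ltr_pipeline(sim, cands$a, cands$b, reference = sim$masters, ...)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Random interval set on one scaffold for interval-arithmetic oracles.
rand_intervals <- function(n, scaffold = "s", max_pos = 5000, max_len = 1200) {
  st <- sample.int(max_pos, n, replace = TRUE) - 1L
  en <- st + sample.int(max_len, n, replace = TRUE)
  data.frame(scaffold = scaffold, start = st, end = en, stringsAsFactors = FALSE)
}

# Plant a row of sequences separated by background gaps and return the genome
# plus the corresponding hit table (used to test pairing without the scanner).
plant_hits <- function(seqs, gaps, scaffold = "s", strand = "+", lead = 1000) {
  stopifnot(length(gaps) == length(seqs) - 1 || length(seqs) == 1)
  genome_parts <- rand_dna(lead)
  start <- integer(0); end <- integer(0)
  pos <- lead
  for (i in seq_along(seqs)) {
    start <- c(start, pos)
    end <- c(end, pos + nchar(seqs[i]))
    genome_parts <- c(genome_parts, seqs[i])
    pos <- pos + nchar(seqs[i])
    gap <- if (i < length(seqs)) gaps[i] else 500
    genome_parts <- c(genome_parts, rand_dna(gap))
    pos <- pos + gap
  }
  genome <- setNames(paste(genome_parts, collapse = ""), scaffold)
  hits <- data.frame(
    hit_id = sprintf("hit_%05d", seq_along(seqs)), scaffold = scaffold,
    start = start, end = end, strand = strand,
    library_id = "L", family = "ERVK", identity = 100, query_coverage = 100,
    score = nchar(seqs), stringsAsFactors = FALSE)
  list(genome = genome, hits = hits)
}

# Number of random pairing instances (<= max_hits hits each) on which
# pair_ltrs() disagrees with a plain-loop mutual-best oracle that recomputes
# best partners from the identity matrix after every extraction.
rbh_oracle_mismatches <- function(n_instances, max_hits = 20, window = 8000,
                                  threshold = 85) {
  n_wrong <- 0
  for (rep in seq_len(n_instances)) {
    n <- sample(3:max_hits, 1)
    masters <- replicate(3, rand_dna(120))
    seqs <- vapply(sample(1:3, n, TRUE), function(m) {
      soloLTR:::mutate_dna(masters[m], runif(1, 0, 0.15))
    }, "")
    p <- plant_hits(seqs, gaps = sample(200:6000, n - 1, TRUE))
    got <- pair_ltrs(p$hits, p$genome, window = window,
                     min_pair_identity = threshold)

    h <- p$hits
    sq <- vapply(seq_len(n), function(i) substr(p$genome, h$start[i] + 1, h$end[i]), "")
    idm <- matrix(-Inf, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      gap <- h$start[j] - h$end[i]
      if (gap >= 0 && gap <= window) {
        idv <- soloLTR:::global_identity(sq[i], sq[j])
        if (idv >= threshold) idm[i, j] <- idm[j, i] <- idv
      }
    }
    gapm <- outer(seq_len(n), seq_len(n),
                  function(i, j) abs(ifelse(i < j, h$start[j] - h$end[i],
                                            h$start[i] - h$end[j])))
    alive <- rep(TRUE, n); oracle <- NULL
    repeat {
      best <- rep(NA_integer_, n)
      for (i in which(alive)) {
        cand <- which(alive & is.finite(idm[i, ]))
        cand <- cand[cand != i]
        if (!length(cand)) next
        cand <- cand[order(-idm[i, cand], gapm[i, cand], h$start[cand])]
        best[i] <- cand[1]
      }
      mutual <- which(!is.na(best) & best[best] == seq_len(n) & seq_len(n) < best)
      if (!length(mutual)) break
      sel <- mutual[order(-idm[cbind(mutual, best[mutual])],
                          gapm[cbind(mutual, best[mutual])],
                          pmin(h$start[mutual], h$start[best[mutual]]))][1]
      oracle <- rbind(oracle, c(sel, best[sel]))
      alive[c(sel, best[sel])] <- FALSE
    }
    got_pairs <- if (nrow(got$pairs)) {
      m <- cbind(match(got$pairs$left_id, h$hit_id), match(got$pairs$right_id, h$hit_id))
      m[order(m[, 1]), , drop = FALSE]
    } else matrix(integer(0), ncol = 2)
    oracle_pairs <- if (is.null(oracle)) matrix(integer(0), ncol = 2) else {
      o <- t(apply(oracle, 1, sort)); o[order(o[, 1]), , drop = FALSE]
    }
    if (!identical(unname(got_pairs), unname(oracle_pairs))) n_wrong <- n_wrong + 1
  }
  n_wrong
}
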