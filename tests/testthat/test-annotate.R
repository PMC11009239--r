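test_that("candidate intersection keeps in-range overlap intervals only", {
  a <- data.frame(scaffold = "s", start = 100, end = 600)
  b <- data.frame(scaffold = "s", start = 300, end = 900)
  expect_equal(intersect_candidates(a, b),
               data.frame(scaffold = "s", start = 300, end = 600))

  a2 <- data.frame(scaffold = "s", start = 100, end = 180)
  expect_equal(nrow(intersect_candidates(a2, a2)), 0)  # 80 bp < 100 bp floor

  bad <- data.frame(scaffold = "s", start = 500, end = 400)
  expect_error(intersect_candidates(bad, b), "malformed")
})

test_that("candidate intersection equals the all-pairs brute-force filter", {
  set.seed(101)
  for (rep in 1:3) {
    a <- rand_intervals(200)
    b <- rand_intervals(200)
    got <- intersect_candidates(a, b)
    exp <- NULL
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(nrow(b))) {
        st <- max(a$start[i], b$start[j]); en <- min(a$end[i], b$end[j])
        if (en - st >= 100 && en - st <= 1000) {
          exp <- rbind(exp, data.frame(scaffold = "s", start = st, end = en))
        }
      }
    }
    exp <- unique(exp[order(exp$start, exp$end), ])
    rownames(exp) <- NULL
    expect_equal(got, exp)
  }
})

test_that("library clustering removes redundant sequences greedily, longest first", {
  set.seed(55)
  s1 <- rand_dna(300)
  lib <- build_library(data.frame(id = c("x", "y"), family = "ERVK",
                                  sequence = c(s1, s1)))
  expect_equal(nrow(lib), 1)

  s2 <- rand_dna(300)  # unrelated: far below 95%
  lib2 <- build_library(data.frame(id = c("x", "y"), family = "ERVK",
                                   sequence = c(s1, s2)))
  expect_equal(nrow(lib2), 2)

  expect_message(
    lib3 <- build_library(data.frame(id = c("a", "b"), family = "ERVK",
                                     sequence = c(s1, rand_dna(50)))),
    "rejected 1")
  expect_equal(lib3$id, "a")
  expect_warning(build_library(data.frame(id = character(0), family = character(0),
                                          sequence = character(0))), "empty")
})

test_that("library clustering matches an exhaustive pairwise-identity oracle", {
  suppressMessages(library(Biostrings))
  set.seed(77)
  mat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -2, baseOnly = TRUE)
  pid_ref <- function(a, b) {
    # shorter aligned globally against the longer, Biostrings as the oracle
    if (nchar(a) < nchar(b)) { t <- a; a <- b; b <- t }
    aln <- pairwiseAlignment(DNAString(b), DNAString(a), type = "global",
                             substitutionMatrix = mat, gapOpening = 3, gapExtension = 2)
    pid(aln, type = "PID1")
  }
  base <- replicate(12, rand_dna(sample(150:250, 1)))
  dups <- vapply(sample(base, 8, replace = TRUE), function(s) {
    ch <- strsplit(s, "")[[1]]
    k <- max(1, round(0.02 * length(ch)))   # ~98% identical duplicates
    pos <- sample(length(ch), k)
    ch[pos] <- vapply(ch[pos], function(x) sample(setdiff(c("A","C","G","T"), x), 1), "")
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
  seqs <- data.frame(id = sprintf("q%02d", 1:20), family = "ERVK",
                     sequence = c(base, dups), stringsAsFactors = FALSE)
  got <- build_library(seqs)$id

  ord <- seqs[order(-nchar(seqs$sequence), seqs$id), ]
  kept <- character(0); kept_seq <- character(0)
  for (i in seq_len(nrow(ord))) {
    if (all(vapply(kept_seq, function(r) pid_ref(ord$sequence[i], r), 1) < 95)) {
      kept <- c(kept, ord$id[i]); kept_seq <- c(kept_seq, ord$sequence[i])
    }
  }
  expect_equal(got, kept)
})

test_that("library building is idempotent on its own entries", {
  set.seed(78)
  seqs <- data.frame(id = sprintf("q%d", 1:10), family = "ERVK",
                     sequence = replicate(10, rand_dna(sample(120:400, 1))))
  lib <- build_library(seqs)
  lib2 <- build_library(as.data.frame(lib))
  expect_equal(lib2$id, lib$id)
})

test_that("the scanner finds an exact library copy at full identity and coverage", {
  set.seed(91)
  entry <- rand_dna(300)
  genome <- c(chr = paste0(rand_dna(5000), entry, rand_dna(5000)))
  lib <- data.frame(id = "L1", family = "ERVK", sequence = entry)
  hits <- scan_genome(genome, lib)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 5000)
  expect_equal(hits$end, 5300)
  expect_equal(hits$identity, 100)
  expect_equal(hits$query_coverage, 100)
  expect_equal(hits$strand, "+")

  # and its reverse complement on the minus strand
  genome2 <- c(chr = paste0(rand_dna(3000), soloLTR:::revcomp(entry), rand_dna(3000)))
  hits2 <- scan_genome(genome2, lib)
  expect_equal(nrow(hits2), 1)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$start, 3000)
})

test_that("pure background produces no hits (empirical null)", {
  set.seed(92)
  entry <- rand_dna(300)
  lib <- data.frame(id = "L1", family = "ERVK", sequence = entry)
  fp <- 0
  for (k in 1:20) {
    genome <- c(chr = rand_dna(50000))
    fp <- fp + nrow(scan_genome(genome, lib))
  }
  expect_equal(fp, 0)
})

test_that("heavily diverged copies fall below the detection thresholds", {
  set.seed(93)
  entry <- rand_dna(300)
  lib <- data.frame(id = "L1", family = "ERVK", sequence = entry)
  mut <- soloLTR:::mutate_dna(entry, 0.45)
  genome <- c(chr = paste0(rand_dna(3000), mut, rand_dna(3000)))
  expect_equal(nrow(scan_genome(genome, lib)), 0)
})

test_that("raising scan thresholds never increases the hit count", {
  sim <- small_sim(seed = 94, n_full = 3, n_solo = 3, divergence = 0.1,
                   genome_length = 60000, n_scaffolds = 1)
  lib <- as.data.frame(sim$sources)
  n <- vapply(c(65, 80, 92), function(mi) nrow(scan_genome(sim, lib, min_identity = mi)), 1L)
  expect_true(all(diff(n) <= 0))
  nq <- vapply(c(80, 90, 99), function(qc) nrow(scan_genome(sim, lib, min_qcov = qc)), 1L)
  expect_true(all(diff(nq) <= 0))
})

test_that("hit clustering keeps the single best hit per overlap component", {
  h <- data.frame(
    scaffold = "s", start = c(100, 150, 180, 900),
    end = c(400, 450, 480, 1200), strand = "+",
    library_id = c("a", "b", "c", "d"), family = "ERVK",
    identity = c(90, 95, 90, 80), query_coverage = 100,
    score = c(50, 80, 80, 10), stringsAsFactors = FALSE)
  out <- cluster_hits(h)
  expect_equal(nrow(out), 2)
  expect_equal(out$library_id, c("b", "d"))  # score 80 tie broken by identity 95

  # disjoint hits all survive
  h2 <- h[c(1, 4), ]
  expect_equal(nrow(cluster_hits(h2)), 2)
})

test_that("hit clustering equals a brute-force connected-components oracle", {
  set.seed(111)
  for (rep in 1:5) {
    n <- 30
    st <- sample.int(3000, n) - 1L
    h <- data.frame(scaffold = sample(c("s1", "s2"), n, TRUE), start = st,
                    end = st + sample(50:400, n, TRUE), strand = "+",
                    library_id = sprintf("q%d", 1:n), family = "ERVK",
                    identity = round(runif(n, 70, 100), 1), query_coverage = 100,
                    score = sample(10:60, n, TRUE), stringsAsFactors = FALSE)
    got <- cluster_hits(h)

    # oracle: repeated expansion of overlap components, then max selection
    keep <- NULL
    for (s in unique(h$scaffold)) {
      hs <- h[h$scaffold == s, ]
      comp <- seq_len(nrow(hs))
      repeat {
        changed <- FALSE
        for (i in seq_len(nrow(hs))) for (j in seq_len(nrow(hs))) {
          if (hs$start[i] < hs$end[j] && hs$start[j] < hs$end[i] &&
              comp[i] != comp[j]) {
            comp[comp == comp[j]] <- comp[i]; changed <- TRUE
          }
        }
        if (!changed) break
      }
      for (g in unique(comp)) {
        cand <- hs[comp == g, ]
        cand <- cand[order(-cand$score, -cand$identity, cand$start), ]
        keep <- rbind(keep, cand[1, ])
      }
    }
    keep <- keep[order(keep$scaffold, keep$start), ]
    expect_equal(got$library_id, keep$library_id)
    expect_equal(got$start, keep$start)
    # antichain: no two retained hits overlap
    for (s in unique(got$scaffold)) {
      g <- got[got$scaffold == s, ]
      g <- g[order(g$start), ]
      if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
    }
  }
})

test_that("scaffold filtering applies the 20 kb boundary inclusively", {
  h <- data.frame(scaffold = c("a", "b", "c"), start = 0, end = 100, strand = "+",
                  library_id = "q", family = "ERVK", identity = 100,
                  query_coverage = 100, score = 10, stringsAsFactors = FALSE)
  lens <- c(a = 19999, b = 20000, c = 50000)
  expect_message(out <- filter_scaffolds(h, lens), "removed 1")
  expect_equal(out$scaffold, c("b", "c"))
  expect_error(filter_scaffolds(h, lens[1:2]), "unknown")
  expect_equal(nrow(filter_scaffolds(h[0, ], lens)), 0)
})

test_that("scanning a divergence-0 genome recovers every planted LTR interval", {
  sim <- small_sim(seed = 95)
  res <- run_sim_pipeline(sim)
  hits <- res$hits
  truth_iv <- rbind(
    data.frame(scaffold = sim$truth$scaffold, start = sim$truth$ltr1_start,
               end = sim$truth$ltr1_end),
    with(sim$truth[sim$truth$kind == "full_erv", ],
         data.frame(scaffold = scaffold, start = ltr2_start, end = ltr2_end)))
  # recall 1: every planted interval recovered with reciprocal overlap >= 0.95
  for (i in seq_len(nrow(truth_iv))) {
    ov <- hits$scaffold == truth_iv$scaffold[i] &
      pmin(hits$end, truth_iv$end[i]) - pmax(hits$start, truth_iv$start[i]) >=
        0.95 * (truth_iv$end[i] - truth_iv$start[i])
    expect_true(any(ov))
  }
  # precision 1: no hit outside planted intervals (+/- 20 bp)
  for (i in seq_len(nrow(hits))) {
    near <- truth_iv$scaffold == hits$scaffold[i] &
      abs(truth_iv$start - hits$start[i]) <= 20 & abs(truth_iv$end - hits$end[i]) <= 20
    expect_true(any(near))
  }
})

test_that("library FASTA round-trips with family tags in the header", {
  lib <- data.frame(id = c("a", "b"), family = c("ERVK", "ERVL"),
                    sequence = c(rand_dna(120), rand_dna(150)))
  fa <- tempfile(fileext = ".fa")
  write_library_fasta(lib, fa)
  back <- read_library_fasta(fa)
  expect_equal(as.data.frame(back), lib)
})
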