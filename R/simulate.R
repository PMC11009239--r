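#' Simulation configuration for synthetic ERV genomes
#'
#' Parameters describing a synthetic genome carrying planted full-length
#' endogenous retroviruses (TSD + LTR + internal region + LTR + TSD) and
#' solo-LTRs (TSD + LTR + TSD). The background sequence is i.i.d. uniform
#' ACGT; elements never overlap and are kept at least `min_spacing` bp apart
#' so that flanking-sequence analyses (TSD checks) see clean background.
#'
#' Two divergence knobs model two biological clocks:
#' * `insertion_divergence` — substitutions per site separating each
#'   insertion event from its family master sequence. Independent proviral
#'   insertions of one family are never identical in real genomes; repeat
#'   families are conventionally bounded at roughly 80% internal identity,
#'   hence the 0.15 default.
#' * `divergence` — substitutions per site applied independently to each LTR
#'   copy after insertion, i.e. the post-insertion age of the element. At 0
#'   the two LTRs of a provirus are identical strings, as they are at the
#'   moment of integration.
#'
#' @param genome_length total genome size in bp, split across `n_scaffolds`.
#' @param n_scaffolds number of scaffolds.
#' @param ltr_length LTR length in bp; must lie in \[100, 1000\].
#' @param internal_length length of the proviral internal (gag/pol/env) region.
#' @param n_full_erv,n_solo numbers of planted full ERVs and solo-LTRs.
#' @param tsd_length target-site duplication length in bp, in \[4, 6\].
#' @param divergence per-copy substitution rate in \[0, 0.35\].
#' @param insertion_divergence per-insertion substitution rate from the family
#'   master, in \[0, 0.35\].
#' @param families named integer vector: number of master LTR sequences per
#'   ERV family (e.g. `c(ERVK = 2, ERVL = 1)`).
#' @param min_spacing minimum background gap between planted elements and to
#'   scaffold edges, bp.
#' @param seed default random seed used by `simulate_genome()`.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(genome_length = 500000, n_scaffolds = 5,
                       ltr_length = 300, internal_length = 2000,
                       n_full_erv = 10, n_solo = 10, tsd_length = 5,
                       divergence = 0, insertion_divergence = 0.15,
                       families = c(ERVK = 2, ERVL = 1, ERV1 = 1),
                       min_spacing = 100, seed = 1) {
  if (ltr_length < 100 || ltr_length > 1000) .stopf("ltr_length must be in [100, 1000]")
  if (tsd_length < 4 || tsd_length > 6) .stopf("tsd_length must be in [4, 6]")
  if (divergence < 0 || divergence > 0.35) .stopf("divergence must be in [0, 0.35]")
  if (insertion_divergence < 0 || insertion_divergence > 0.35) {
    .stopf("insertion_divergence must be in [0, 0.35]")
  }
  for (nm in c("genome_length", "n_scaffolds", "internal_length",
               "n_full_erv", "n_solo", "min_spacing")) {
    if (!.is_count(get(nm))) .stopf("%s must be a non-negative integer", nm)
  }
  if (n_scaffolds < 1) .stopf("n_scaffolds must be >= 1")
  if (is.null(names(families)) || any(!nzchar(names(families))) || any(families < 1)) {
    .stopf("families must be a named vector of positive per-family master counts")
  }
  structure(list(
    genome_length = as.integer(genome_length), n_scaffolds = as.integer(n_scaffolds),
    ltr_length = as.integer(ltr_length), internal_length = as.integer(internal_length),
    n_full_erv = as.integer(n_full_erv), n_solo = as.integer(n_solo),
    tsd_length = as.integer(tsd_length), divergence = divergence,
    insertion_divergence = insertion_divergence, families = families,
    min_spacing = as.integer(min_spacing), seed = as.integer(seed)),
    class = "sim_config")
}

.empty_truth <- function() {
  data.frame(
    element_id = character(0), kind = character(0), scaffold = character(0),
    strand = character(0), family = character(0), library_id = character(0),
    start = integer(0), end = integer(0),
    ltr1_start = integer(0), ltr1_end = integer(0),
    ltr2_start = integer(0), ltr2_end = integer(0),
    tsd = character(0),
    tsd_left_start = integer(0), tsd_left_end = integer(0),
    tsd_right_start = integer(0), tsd_right_end = integer(0),
    stringsAsFactors = FALSE)
}

# Master LTR (and one internal region) per family; ids follow the
# ">id#FAMILY" library dialect.
.draw_masters <- function(config) {
  ids <- character(0); fams <- character(0); seqs <- character(0)
  for (fam in names(config$families)) {
    k <- config$families[[fam]]
    for (i in seq_len(k)) {
      ids <- c(ids, sprintf("%s_%d", fam, i))
      fams <- c(fams, fam)
      seqs <- c(seqs, random_dna(config$ltr_length))
    }
  }
  internals <- setNames(
    vapply(names(config$families), function(f) random_dna(config$internal_length), ""),
    names(config$families))
  list(ltr = data.frame(id = ids, family = fams, sequence = seqs,
                        stringsAsFactors = FALSE),
       internal = internals)
}

#' Simulate a genome with planted ERVs and solo-LTRs
#'
#' Generates `n_scaffolds` scaffolds of i.i.d. uniform ACGT background and
#' plants `n_full_erv` full proviruses (TSD + LTR + internal + LTR + TSD) and
#' `n_solo` solo-LTRs (TSD + LTR + TSD) at rejection-sampled non-overlapping
#' positions. The two LTR copies of a provirus derive from one master
#' sequence: a per-insertion variant of the family master is drawn at rate
#' `insertion_divergence`, then each copy is independently mutated at rate
#' `divergence`. Both TSD copies are identical at planting. Every coordinate
#' is recorded exactly in the truth table (0-based half-open; `start`/`end`
#' bound the LTR region, the TSD intervals sit immediately outside).
#'
#' @param config a [sim_config()].
#' @param seed random seed; defaults to `config$seed`.
#' @return an object of class `sim_genome`: list with `genome` (named
#'   character vector of scaffold sequences), `truth` (data.frame, one row per
#'   planted element), `masters` (family master LTRs), `sources` (the
#'   per-insertion variant each element's copies derive from; `library_id` in
#'   the truth table points here), `config`.
#' @export
simulate_genome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  .set_seed(seed)
  masters <- .draw_masters(config)

  per <- floor(config$genome_length / config$n_scaffolds)
  scaff_len <- rep(per, config$n_scaffolds)
  scaff_len[config$n_scaffolds] <- config$genome_length - per * (config$n_scaffolds - 1L)
  scaff_names <- sprintf("scaffold_%d", seq_len(config$n_scaffolds))
  names(scaff_len) <- scaff_names

  n_elem <- config$n_full_erv + config$n_solo
  kinds <- c(rep("full_erv", config$n_full_erv), rep("solo_ltr", config$n_solo))
  truth <- .empty_truth()
  placed <- lapply(scaff_names, function(s) matrix(numeric(0), ncol = 2))
  names(placed) <- scaff_names

  t <- config$tsd_length; L <- config$ltr_length; I <- config$internal_length
  sp <- config$min_spacing

  sources <- NULL
  rows <- vector("list", n_elem)
  for (i in seq_len(n_elem)) {
    kind <- kinds[i]
    foot <- if (kind == "full_erv") 2L * t + 2L * L + I else 2L * t + L
    ok <- FALSE
    for (try in seq_len(1000L)) {
      s <- sample(scaff_names, 1L, prob = scaff_len)
      lo <- sp; hi <- scaff_len[[s]] - sp - foot
      if (hi < lo) next
      p <- lo + floor(runif(1) * (hi - lo + 1L))
      iv <- placed[[s]]
      if (nrow(iv) == 0 || all(p >= iv[, 2] + sp | p + foot + sp <= iv[, 1])) {
        placed[[s]] <- rbind(iv, c(p, p + foot))
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      .stopf("placement failure: could not place element %d of %d (kind %s, %d bp) %s",
             i, n_elem, kind, foot, "after 1000 attempts; genome too small or too crowded")
    }
    midx <- sample(nrow(masters$ltr), 1L)
    fam <- masters$ltr$family[midx]
    strand <- sample(c("+", "-"), 1L)
    rows[[i]] <- list(i = i, kind = kind, scaffold = s, p = p, foot = foot,
                      midx = midx, fam = fam, strand = strand)
  }

  # Build sequences and truth records.
  scaffolds <- setNames(vapply(scaff_len, random_dna, ""), scaff_names)
  for (r in rows) {
    tsd <- random_dna(t)
    variant <- mutate_dna(masters$ltr$sequence[r$midx], config$insertion_divergence)
    src_id <- sprintf("src_%03d", r$i)
    sources <- rbind(sources, data.frame(
      id = src_id, family = r$fam, sequence = variant, stringsAsFactors = FALSE))
    copy1 <- mutate_dna(variant, config$divergence)
    if (r$kind == "full_erv") {
      copy2 <- mutate_dna(variant, config$divergence)
      core <- paste0(copy1, masters$internal[[r$fam]], copy2)
    } else {
      core <- copy1
    }
    if (r$strand == "-") core <- revcomp(core)
    planted <- paste0(tsd, core, tsd)
    stopifnot(nchar(planted) == r$foot)
    sq <- scaffolds[[r$scaffold]]
    scaffolds[[r$scaffold]] <- paste0(
      substr(sq, 1L, r$p), planted, substr(sq, r$p + r$foot + 1L, nchar(sq)))

    p <- r$p
    start <- p + t
    if (r$kind == "full_erv") {
      end <- start + 2L * L + I
      ltr1 <- c(start, start + L)
      ltr2 <- c(end - L, end)
    } else {
      end <- start + L
      ltr1 <- c(start, end)
      ltr2 <- c(NA_integer_, NA_integer_)
    }
    truth <- rbind(truth, data.frame(
      element_id = sprintf("elem_%03d", r$i), kind = r$kind, scaffold = r$scaffold,
      strand = r$strand, family = r$fam, library_id = src_id,
      start = start, end = end,
      ltr1_start = ltr1[1], ltr1_end = ltr1[2],
      ltr2_start = ltr2[1], ltr2_end = ltr2[2],
      tsd = tsd, tsd_left_start = p, tsd_left_end = p + t,
      tsd_right_start = end, tsd_right_end = end + t,
      stringsAsFactors = FALSE))
  }
  truth <- truth[order(truth$scaffold, truth$start), , drop = FALSE]
  rownames(truth) <- NULL

  structure(list(genome = scaffolds, truth = truth,
                 masters = masters$ltr, sources = sources, config = config),
            class = "sim_genome")
}

#' Emit two candidate LTR annotation sets from a simulated genome
#'
#' Emulates the two independent annotation sources whose intersection seeds
#' the LTR library. Each set contains every planted LTR copy interval, with
#' each boundary independently perturbed by up to `jitter` bp (outward or
#' inward, uniform), plus `n_spurious` random background intervals per set.
#'
#' @param sim a `sim_genome`.
#' @param jitter maximum per-boundary perturbation in bp (default 0: both
#'   sources call boundaries exactly).
#' @param n_spurious random background intervals added per set (length drawn
#'   in \[100, 1000\]).
#' @param seed random seed.
#' @return list with interval data.frames `a` and `b`.
#' @export
candidate_sets <- function(sim, jitter = 0, n_spurious = 0, seed = 1) {
  stopifnot(inherits(sim, "sim_genome"))
  .set_seed(seed)
  truth <- sim$truth
  iv <- data.frame(scaffold = truth$scaffold, start = truth$ltr1_start,
                   end = truth$ltr1_end, stringsAsFactors = FALSE)
  full <- truth[truth$kind == "full_erv", , drop = FALSE]
  if (nrow(full)) {
    iv <- rbind(iv, data.frame(scaffold = full$scaffold, start = full$ltr2_start,
                               end = full$ltr2_end, stringsAsFactors = FALSE))
  }
  slen <- setNames(nchar(sim$genome), names(sim$genome))
  one_set <- function() {
    out <- iv
    if (jitter > 0) {
      out$start <- pmax(0L, out$start + sample(seq.int(-jitter, jitter), nrow(out), TRUE))
      out$end <- pmin(slen[out$scaffold], out$end + sample(seq.int(-jitter, jitter), nrow(out), TRUE))
      out <- out[out$start < out$end, , drop = FALSE]
    }
    for (k in seq_len(n_spurious)) {
      s <- sample(names(slen), 1L)
      w <- sample(100:1000, 1L)
      if (slen[[s]] <= w) next
      st <- sample.int(slen[[s]] - w, 1L) - 1L
      out <- rbind(out, data.frame(scaffold = s, start = st, end = st + w,
                                   stringsAsFactors = FALSE))
    }
    out <- .sort_intervals(out)
    rownames(out) <- NULL
    out
  }
  list(a = one_set(), b = one_set())
}

#' Convert planted full ERVs into solo-LTRs by unequal recombination
#'
#' Emulates unequal homologous recombination between the two LTRs of a
#' provirus: the internal region and one LTR are deleted in place, leaving a
#' single LTR (the left genomic copy, by convention) between the original TSD
#' copies. A random `fraction` of the full ERVs is converted; all downstream
#' truth coordinates on the affected scaffolds are shifted consistently and
#' the background sequence is untouched byte-for-byte.
#'
#' @param sim a `sim_genome`.
#' @param fraction proportion of full ERVs to convert, in \[0, 1\].
#' @param seed random seed.
#' @return a new `sim_genome` with updated `genome` and `truth`.
#' @export
simulate_recombination <- function(sim, fraction, seed = 1) {
  stopifnot(inherits(sim, "sim_genome"))
  if (fraction < 0 || fraction > 1) .stopf("fraction must be in [0, 1]")
  .set_seed(seed)
  truth <- sim$truth
  genome <- sim$genome
  full_idx <- which(truth$kind == "full_erv")
  k <- round(fraction * length(full_idx))
  if (k == 0) return(sim)
  conv <- sort(sample(full_idx, k))

  # Deletion of [ltr1_end, ltr2_end) per converted element; apply right-to-left
  # per scaffold so earlier coordinates stay valid.
  conv <- conv[order(truth$scaffold[conv], -truth$start[conv])]
  for (i in conv) {
    s <- truth$scaffold[i]
    del_start <- truth$ltr1_end[i]
    del_end <- truth$ltr2_end[i]
    dlen <- del_end - del_start
    sq <- genome[[s]]
    genome[[s]] <- paste0(substr(sq, 1L, del_start),
                          substr(sq, del_end + 1L, nchar(sq)))
    shift_cols <- c("start", "end", "ltr1_start", "ltr1_end", "ltr2_start",
                    "ltr2_end", "tsd_left_start", "tsd_left_end",
                    "tsd_right_start", "tsd_right_end")
    later <- which(truth$scaffold == s & truth$start >= del_end & seq_len(nrow(truth)) != i)
    for (cl in shift_cols) truth[later, cl] <- truth[later, cl] - dlen
    truth$kind[i] <- "solo_ltr"
    truth$end[i] <- del_start
    truth$ltr2_start[i] <- NA_integer_
    truth$ltr2_end[i] <- NA_integer_
    truth$tsd_right_start[i] <- del_start
    truth$tsd_right_end[i] <- del_start + nchar(truth$tsd[i])
  }
  truth <- truth[order(truth$scaffold, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  structure(list(genome = genome, truth = truth, masters = sim$masters,
                 config = sim$config), class = "sim_genome")
}

#' Simulate population-level insertion polymorphism and coverage tracks
#'
#' A random `polymorphic_fraction` of the solo-LTRs in `sim` is made
#' polymorphic: presence/absence is drawn per individual with probability 0.5,
#' re-drawn until at least one carrier and one non-carrier exist. All other
#' solo-LTRs are present in every individual. Per-individual depth tracks over
#' the reference coordinate space are Poisson(`depth`) per position, set to 0
#' across the interval of an element the individual lacks (flanking sequence
#' stays covered).
#'
#' @param sim a `sim_genome`.
#' @param n_individuals number of individuals (>= 2 when
#'   `polymorphic_fraction > 0`).
#' @param polymorphic_fraction proportion of solo-LTRs made polymorphic.
#' @param depth mean sequencing depth.
#' @param seed random seed.
#' @return class `sim_population`: list with `presence` (logical element x
#'   individual matrix), `coverage` (per individual, per scaffold integer
#'   depth vectors; position i is entry i + 1), `solos` (the solo truth rows).
#' @export
simulate_population <- function(sim, n_individuals, polymorphic_fraction = 0.1,
                                depth = 20, seed = 1) {
  stopifnot(inherits(sim, "sim_genome"))
  if (!.is_count(n_individuals) || n_individuals < 1) .stopf("n_individuals must be >= 1")
  if (polymorphic_fraction < 0 || polymorphic_fraction > 1) {
    .stopf("polymorphic_fraction must be in [0, 1]")
  }
  if (polymorphic_fraction > 0 && n_individuals < 2) {
    .stopf("polymorphic elements need n_individuals >= 2")
  }
  .set_seed(seed)
  solos <- sim$truth[sim$truth$kind == "solo_ltr", , drop = FALSE]
  inds <- sprintf("ind_%02d", seq_len(n_individuals))
  presence <- matrix(TRUE, nrow = nrow(solos), ncol = n_individuals,
                     dimnames = list(solos$element_id, inds))
  n_poly <- round(polymorphic_fraction * nrow(solos))
  poly <- if (n_poly > 0) sort(sample(nrow(solos), n_poly)) else integer(0)
  for (i in poly) {
    repeat {
      v <- runif(n_individuals) < 0.5
      if (any(v) && any(!v)) break
    }
    presence[i, ] <- v
  }

  coverage <- lapply(inds, function(ind) {
    lapply(sim$genome, function(sq) rpois(nchar(sq), depth))
  })
  names(coverage) <- inds
  for (i in seq_len(nrow(solos))) {
    absent <- inds[!presence[i, ]]
    for (ind in absent) {
      s <- solos$scaffold[i]
      coverage[[ind]][[s]][(solos$start[i] + 1L):solos$end[i]] <- 0L
    }
  }
  structure(list(presence = presence, coverage = coverage, solos = solos),
            class = "sim_population")
}

.resolve_node <- function(tree, label) {
  ntip <- length(tree$tip.label)
  if (label %in% tree$tip.label) return(match(label, tree$tip.label))
  if (identical(label, "root")) return(ntip + 1L)
  if (!is.null(tree$node.label) && label %in% tree$node.label) {
    return(ntip + match(label, tree$node.label))
  }
  .stopf("unknown tree node '%s' (use a tip label, a node label, or 'root')", label)
}

.tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .tips_under, tree = tree))
}

#' Simulate orthologous solo-LTR insertions across a species tree
#'
#' Elements (solo-LTR type: TSD + LTR + TSD) are planted on branches of the
#' tree: an element assigned to a branch is present, at the orthologous
#' position, in every tip descending from that branch. All tips share one
#' ancestral background sequence; per-tip genomes are the background with the
#' tip's elements inserted, so alignment blocks can be emitted from exact
#' coordinate bookkeeping rather than from an aligner. Blocks are of two
#' kinds: one block per element covering its footprint in every carrier tip,
#' and background blocks between insertion anchors covering all tips.
#'
#' @param tree an `ape::phylo` or a newick string. Internal nodes may carry
#'   labels; the root can always be addressed as `"root"`.
#' @param branch_counts named integer vector of element counts per branch;
#'   names are tip labels, node labels or `"root"`.
#' @param config a [sim_config()] supplying background length (single scaffold
#'   `"chr1"` per tip), `ltr_length`, `tsd_length`, divergence knobs and
#'   families.
#' @param seed random seed.
#' @return class `sim_species_set`: list with `genomes` (named character
#'   vector, one sequence per tip), `truth` (data.frame with a `species`
#'   column and an `origin` branch label per element), `blocks` (alignment
#'   block table: block_id, species, scaffold, start, end, strand, src_size),
#'   `tree`.
#' @export
simulate_species_set <- function(tree, branch_counts, config, seed = 1) {
  if (is.character(tree)) {
    tree <- tryCatch(suppressWarnings(ape::read.tree(text = tree)),
                     error = function(e) NULL)
    if (is.null(tree) || is.null(tree$edge)) .stopf("malformed newick tree")
  }
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  if (length(tree$tip.label) < 2) .stopf("tree must have >= 2 tips")
  if (is.null(names(branch_counts))) .stopf("branch_counts must be named")
  .set_seed(seed)

  t <- config$tsd_length; L <- config$ltr_length
  foot <- 2L * t + L
  G <- config$genome_length
  masters <- .draw_masters(config)

  origins <- rep(names(branch_counts), branch_counts)
  n_elem <- length(origins)
  # Anchor = position in ancestral background coordinates where the element
  # inserts; anchors are spaced so background blocks are non-trivial.
  min_gap <- 50L
  slack <- G - 2L * min_gap - (n_elem + 1L) * min_gap
  if (slack < n_elem) .stopf("genome_length too small for %d elements", n_elem)
  # distinct draws spread by min_gap: guarantees pairwise spacing >= min_gap
  anchors <- sort(sample.int(slack, n_elem)) +
    min_gap + min_gap * seq_len(n_elem)

  carrier_tips <- lapply(origins, function(o) {
    node <- .resolve_node(tree, o)
    .tips_under(tree, node)
  })

  elem <- data.frame(
    element_id = sprintf("elem_%03d", seq_len(n_elem)),
    origin = origins, anchor = anchors, stringsAsFactors = FALSE)
  elem$family <- NA_character_; elem$library_id <- NA_character_
  elem$tsd <- vapply(seq_len(n_elem), function(i) random_dna(t), "")
  midx <- sample(nrow(masters$ltr), n_elem, replace = TRUE)
  elem$family <- masters$ltr$family[midx]
  elem$library_id <- masters$ltr$id[midx]
  variants <- vapply(midx, function(m) {
    mutate_dna(masters$ltr$sequence[m], config$insertion_divergence)
  }, "")

  background <- random_dna(G)
  tips <- tree$tip.label
  genomes <- setNames(character(length(tips)), tips)
  truth <- NULL
  blocks <- NULL
  bid <- 0L

  tip_elem_start <- matrix(NA_integer_, nrow = n_elem, ncol = length(tips),
                           dimnames = list(elem$element_id, tips))
  for (tp in tips) {
    has <- vapply(carrier_tips, function(ct) tp %in% ct, TRUE)
    idx <- which(has)
    pieces <- character(0)
    pos <- 0L   # current cursor in ancestral background
    out_len <- 0L
    for (i in idx) {
      a <- elem$anchor[i]
      pieces <- c(pieces, substr(background, pos + 1L, a))
      out_len <- out_len + (a - pos)
      copy <- mutate_dna(variants[i], config$divergence)
      planted <- paste0(elem$tsd[i], copy, elem$tsd[i])
      tip_elem_start[i, tp] <- out_len           # footprint start in tip coords
      pieces <- c(pieces, planted)
      out_len <- out_len + foot
      pos <- a
    }
    pieces <- c(pieces, substr(background, pos + 1L, G))
    genomes[[tp]] <- paste(pieces, collapse = "")
    if (length(idx)) {
      fs <- tip_elem_start[idx, tp]
      truth <- rbind(truth, data.frame(
        species = tp, element_id = elem$element_id[idx], origin = elem$origin[idx],
        family = elem$family[idx], library_id = elem$library_id[idx],
        scaffold = "chr1", strand = "+",
        start = fs + t, end = fs + t + L,
        tsd = elem$tsd[idx],
        tsd_left_start = fs, tsd_left_end = fs + t,
        tsd_right_start = fs + t + L, tsd_right_end = fs + foot,
        stringsAsFactors = FALSE))
    }
  }

  tip_len <- setNames(nchar(genomes), tips)

  # Element blocks: the footprint interval in every carrier tip.
  for (i in seq_len(n_elem)) {
    bid <- bid + 1L
    carr <- intersect(tips, carrier_tips[[i]])
    blocks <- rbind(blocks, data.frame(
      block_id = sprintf("block_%04d", bid), species = carr, scaffold = "chr1",
      start = tip_elem_start[i, carr], end = tip_elem_start[i, carr] + foot,
      strand = "+", src_size = tip_len[carr], stringsAsFactors = FALSE))
  }
  # Background blocks between consecutive anchors, covering all tips. A tip's
  # coordinate offset inside a segment is the total length it has inserted at
  # anchors left of the segment.
  bounds <- c(0L, elem$anchor, G)
  for (k in seq_len(length(bounds) - 1L)) {
    seg_start <- bounds[k]; seg_end <- bounds[k + 1L]
    if (seg_end <= seg_start) next
    bid <- bid + 1L
    offs <- vapply(tips, function(tp) {
      ins <- which(!is.na(tip_elem_start[, tp]) & elem$anchor <= seg_start)
      length(ins) * foot
    }, 1L)
    blocks <- rbind(blocks, data.frame(
      block_id = sprintf("block_%04d", bid), species = tips, scaffold = "chr1",
      start = seg_start + offs, end = seg_end + offs,
      strand = "+", src_size = tip_len[tips], stringsAsFactors = FALSE))
  }
  rownames(truth) <- NULL; rownames(blocks) <- NULL
  structure(list(genomes = genomes, truth = truth, blocks = blocks,
                 tree = tree, elements = elem),
            class = "sim_species_set")
}

#' Score a pair/solo partition against simulator truth
#'
#' Matches each planted element's LTR interval(s) to classified hits by
#' reciprocal positional overlap and asks whether the element was recovered
#' with the correct structure: a planted full ERV must have its two LTR copies
#' joined in one pair; a planted solo-LTR must be recovered as a solo.
#'
#' @param partition result of [pair_ltrs()].
#' @param truth truth table from [simulate_genome()].
#' @param tol positional tolerance in bp when matching hit to planted
#'   interval boundaries.
#' @return list with `per_element` (data.frame: element_id, kind, recovered
#'   classification) and `accuracy` (fraction of planted elements recovered
#'   with the correct classification).
#' @export
evaluate_partition <- function(partition, truth, tol = 20) {
  match_iv <- function(scaffold, start, end, tab) {
    i <- which(tab$scaffold == scaffold &
                 abs(tab$start - start) <= tol & abs(tab$end - end) <= tol)
    if (length(i)) i[1] else NA_integer_
  }
  pairs <- partition$pairs; solos <- partition$solos
  res <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    if (tr$kind == "full_erv") {
      hit <- NA_integer_
      if (nrow(pairs)) {
        hit <- which(pairs$scaffold == tr$scaffold &
                       abs(pairs$left_start - tr$ltr1_start) <= tol &
                       abs(pairs$left_end - tr$ltr1_end) <= tol &
                       abs(pairs$right_start - tr$ltr2_start) <= tol &
                       abs(pairs$right_end - tr$ltr2_end) <= tol)
        hit <- if (length(hit)) hit[1] else NA_integer_
      }
      res[i] <- if (!is.na(hit)) "pair" else "other"
    } else {
      hit <- if (nrow(solos)) match_iv(tr$scaffold, tr$ltr1_start, tr$ltr1_end, solos) else NA
      res[i] <- if (!is.na(hit)) "solo" else "other"
    }
  }
  correct <- (truth$kind == "full_erv" & res == "pair") |
    (truth$kind == "solo_ltr" & res == "solo")
  list(per_element = data.frame(element_id = truth$element_id, kind = truth$kind,
                                recovered = res, correct = correct,
                                stringsAsFactors = FALSE),
       accuracy = mean(correct))
}
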