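# Cross-species sharing of solo-LTRs from whole-genome-alignment blocks,
# ancestor attribution on a species tree, and population presence/absence
# calls from coverage.

.solo_table <- function(solos) {
  if (inherits(solos, "ltr_partition")) solos <- solos$solos
  .check_intervals(solos, "solo-LTR set")
  if (is.null(solos$element_id)) {
    solos$element_id <- if (!is.null(solos$hit_id)) solos$hit_id
      else sprintf("%s:%d-%d", solos$scaffold, solos$start, solos$end)
  }
  solos
}

#' Classify solo-LTRs as shared vs species-specific from alignment blocks
#'
#' A solo-LTR on the reference genome is *shared* iff at least `min_overlap`
#' of its interval is covered by alignment blocks that also contain at least
#' one clade species other than the reference; every such species is listed
#' in `shared_with`. Blocks are rows of a long-format table (one row per
#' species per block, MAF semantics): `block_id`, `species`, `scaffold`,
#' `start`, `end`.
#'
#' @param solos solo-LTR intervals on the reference genome (a data.frame with
#'   `scaffold`/`start`/`end` and optionally `element_id`, or an
#'   `ltr_partition`).
#' @param blocks alignment block table.
#' @param reference reference species id (must appear in qualifying blocks'
#'   species rows for coordinates to be interpretable).
#' @param clade_species character vector: the clade within which sharing is
#'   assessed (the reference may be included; it is ignored as a partner).
#' @param min_overlap minimum covered fraction of the solo interval
#'   (default 0.5).
#' @param known_species optional universe of valid species ids; blocks
#'   referencing anything else raise an error.
#' @return data.frame: `element_id`, `status` (`shared` /
#'   `species_specific`), `shared_with` (comma-separated species),
#'   `coverage` (covered fraction).
#' @export
classify_sharing <- function(solos, blocks, reference, clade_species,
                             min_overlap = 0.5, known_species = NULL) {
  solos <- .solo_table(solos)
  if (!all(c("block_id", "species", "scaffold", "start", "end") %in% names(blocks))) {
    .stopf("blocks must have columns block_id/species/scaffold/start/end")
  }
  if (!is.null(known_species)) {
    bad <- setdiff(unique(blocks$species), known_species)
    if (length(bad)) .stopf("blocks reference unknown species: %s", paste(bad, collapse = ", "))
  }
  partners <- setdiff(clade_species, reference)
  ref_rows <- blocks[blocks$species == reference, , drop = FALSE]
  # Which blocks carry at least one clade partner?
  partner_species <- split(blocks$species[blocks$species %in% partners],
                           blocks$block_id[blocks$species %in% partners])
  out <- data.frame(element_id = solos$element_id,
                    status = "species_specific",
                    shared_with = "", coverage = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(solos))) {
    rr <- ref_rows[ref_rows$scaffold == solos$scaffold[i] &
                     ref_rows$end > solos$start[i] &
                     ref_rows$start < solos$end[i], , drop = FALSE]
    if (!nrow(rr)) next
    qual <- rr[rr$block_id %in% names(partner_species), , drop = FALSE]
    if (!nrow(qual)) next
    iv <- IRanges::reduce(IRanges::IRanges(pmax(qual$start, solos$start[i]) + 1L,
                                           pmin(qual$end, solos$end[i])))
    cov <- sum(IRanges::width(iv)) / (solos$end[i] - solos$start[i])
    sw <- sort(unique(unlist(partner_species[qual$block_id], use.names = FALSE)))
    out$coverage[i] <- cov
    if (cov >= min_overlap) {
      out$status[i] <- "shared"
      out$shared_with[i] <- paste(sw, collapse = ",")
    }
  }
  out
}

#' Attribute shared solo-LTRs to ancestral nodes of the species tree
#'
#' A shared element is attributed to the *oldest* listed ancestor node N whose
#' presence pattern (the reference tip plus every species in `shared_with`)
#' spans at least two distinct child clades of N: presence in two daughter
#' lineages is the parsimony condition for the insertion predating N. Shared
#' elements whose pattern is confined to one child clade of every listed node
#' keep attribution `none`.
#'
#' @param calls result of [classify_sharing()].
#' @param tree `ape::phylo` or newick string.
#' @param reference reference species (a tip label).
#' @param node_defs character vector of ancestor node identifiers (node
#'   labels or `"root"`), ordered youngest to oldest; all must lie on the
#'   path from the reference tip to the root.
#' @return `calls` with an `ancestor_attribution` column added.
#' @export
attribute_ancestor <- function(calls, tree, reference, node_defs) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  ref_node <- .resolve_node(tree, reference)
  if (ref_node > ntip) .stopf("reference must be a tip label")
  root <- ntip + 1L
  path_nodes <- ref_node
  nd <- ref_node
  parent_of <- function(x) tree$edge[tree$edge[, 2] == x, 1]
  while (nd != root) {
    nd <- parent_of(nd)
    if (!length(nd)) break
    path_nodes <- c(path_nodes, nd)
  }
  nodes <- vapply(node_defs, .resolve_node, 1L, tree = tree)
  off_path <- node_defs[!(nodes %in% path_nodes)]
  if (length(off_path)) {
    .stopf("node(s) not on the path from '%s' to the root: %s",
           reference, paste(off_path, collapse = ", "))
  }
  clades <- lapply(nodes, function(n) {
    kids <- tree$edge[tree$edge[, 1] == n, 2]
    lapply(kids, .tips_under, tree = tree)
  })
  calls$ancestor_attribution <- "none"
  for (i in seq_len(nrow(calls))) {
    if (calls$status[i] != "shared") next
    present <- c(reference, strsplit(calls$shared_with[i], ",", fixed = TRUE)[[1]])
    present <- present[nzchar(present)]
    attributed <- "none"
    for (k in seq_along(nodes)) {       # node_defs young -> old; keep the oldest
      hit_clades <- sum(vapply(clades[[k]], function(tp) any(present %in% tp), TRUE))
      if (hit_clades >= 2) attributed <- node_defs[k]
    }
    calls$ancestor_attribution[i] <- attributed
  }
  calls
}

#' Call per-individual presence of solo-LTRs from coverage tracks
#'
#' An element is present in an individual iff the fraction of its positions
#' with depth at least `min_depth` (the *breadth*) is at least `min_breadth`.
#'
#' @param solos solo-LTR intervals (see [classify_sharing()]).
#' @param coverage per-individual coverage: a named list (individual ->
#'   named list of per-scaffold integer depth vectors, position i at entry
#'   i + 1), as produced by [simulate_population()] or
#'   [read_coverage_bedgraph()].
#' @param min_breadth minimum covered fraction (default 0.8).
#' @param min_depth minimum depth for a position to count as covered
#'   (default 2).
#' @return class `presence_matrix`: list of three element x individual
#'   matrices `present` (logical), `breadth`, `mean_depth`.
#' @export
call_presence <- function(solos, coverage, min_breadth = 0.8, min_depth = 2) {
  solos <- .solo_table(solos)
  if (is.null(names(coverage))) .stopf("coverage must be a named list (one entry per individual)")
  inds <- names(coverage)
  n <- nrow(solos)
  present <- matrix(NA, n, length(inds), dimnames = list(solos$element_id, inds))
  breadth <- mean_depth <- matrix(NA_real_, n, length(inds),
                                  dimnames = list(solos$element_id, inds))
  for (j in seq_along(inds)) {
    trk <- coverage[[inds[j]]]
    if (is.null(trk)) .stopf("missing coverage track for individual '%s'", inds[j])
    for (i in seq_len(n)) {
      v <- trk[[solos$scaffold[i]]]
      if (is.null(v)) {
        .stopf("individual '%s' has no track for scaffold '%s'", inds[j], solos$scaffold[i])
      }
      d <- v[(solos$start[i] + 1L):solos$end[i]]
      breadth[i, j] <- mean(d >= min_depth)
      mean_depth[i, j] <- mean(d)
      present[i, j] <- breadth[i, j] >= min_breadth
    }
  }
  structure(list(present = present, breadth = breadth, mean_depth = mean_depth),
            class = "presence_matrix")
}

#' Tally exact presence patterns across individuals (UpSet-style, distinct mode)
#'
#' Each solo-LTR contributes to exactly one pattern: the exact subset of
#' individuals carrying it. Patterns with at least `min_size` elements are
#' reported, largest first. Elements that are neither carried by everyone nor
#' by no one are *polymorphic*.
#'
#' @param pm a `presence_matrix` (or a plain logical matrix).
#' @param min_size minimum pattern size to report (default 2).
#' @return list with `patterns` (data.frame: `individuals`
#'   (comma-separated), `n_individuals`, `count`), `polymorphic_count` and
#'   `polymorphic_fraction`.
#' @export
intersection_counts <- function(pm, min_size = 2) {
  m <- if (inherits(pm, "presence_matrix")) pm$present else pm
  if (!is.matrix(m) || nrow(m) == 0) .stopf("presence matrix is empty")
  inds <- colnames(m) %||% sprintf("ind_%02d", seq_len(ncol(m)))
  pat <- apply(m, 1, function(r) paste(inds[r], collapse = ","))
  tab <- table(pat)
  df <- data.frame(individuals = names(tab),
                   n_individuals = vapply(strsplit(names(tab), ",", fixed = TRUE),
                                          function(x) sum(nzchar(x)), 1L),
                   count = as.integer(tab), stringsAsFactors = FALSE)
  df <- df[df$count >= min_size, , drop = FALSE]
  df <- df[order(-df$count, df$individuals), , drop = FALSE]
  rownames(df) <- NULL
  poly <- rowSums(m) > 0 & rowSums(m) < ncol(m)
  list(patterns = df,
       polymorphic_count = sum(poly),
       polymorphic_fraction = mean(poly))
}
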