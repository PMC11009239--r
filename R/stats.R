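# Statistical primitives used by the comparative analyses: Welch's t-test,
# Pearson correlation with a Fisher-z 95% CI, speciation-node depth on a
# species tree, one-sided Fisher enrichment of peak overlap, and
# flanking-gene assignment.

#' Welch's unequal-variance t-test
#'
#' @param x,y numeric samples (each of size >= 2).
#' @param side `"two_sided"`, `"one_sided_greater"` (mean of `x` greater) or
#'   `"one_sided_less"`.
#' @return one-row data.frame: `t`, `df` (Welch-Satterthwaite), `p`, `side`.
#' @export
welch_t <- function(x, y, side = c("two_sided", "one_sided_greater", "one_sided_less")) {
  side <- match.arg(side)
  if (length(x) < 2 || length(y) < 2) .stopf("both samples need >= 2 observations")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) .stopf("both samples have zero variance")
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- switch(side,
    two_sided = 2 * stats::pt(-abs(t), df),
    one_sided_greater = stats::pt(t, df, lower.tail = FALSE),
    one_sided_less = stats::pt(t, df))
  data.frame(t = t, df = df, p = p, side = side, stringsAsFactors = FALSE)
}

#' Pearson correlation with Fisher-z 95% confidence interval
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return one-row data.frame: `r`, `ci_low`, `ci_high` (Fisher z +/- 1.96 /
#'   sqrt(n - 3), back-transformed), `p` (from t = r * sqrt((n - 2) /
#'   (1 - r^2))), `n`.
#' @export
pearson_ci <- function(x, y) {
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  n <- length(x)
  if (n < 3) .stopf("need at least 3 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) .stopf("correlation undefined for constant input")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  z <- atanh(r)
  zse <- 1 / sqrt(n - 3)
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * zse)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), n - 2)
  data.frame(r = r, ci_low = ci[1], ci_high = ci[2], p = p, n = n)
}

#' Speciation-node depth of tips below an ancestor
#'
#' Counts the internal nodes on the path from a named ancestor (inclusive) to
#' each tip (tip excluded) — a proxy for the number of speciation events
#' separating the ancestor from the modern species.
#'
#' @param tree `ape::phylo` or newick string.
#' @param ancestor node identifier (node label or `"root"`).
#' @param tips tip labels; all must descend from `ancestor`.
#' @return data.frame: `species`, `node_count`.
#' @export
speciation_depth <- function(tree, ancestor, tips) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  anc <- .resolve_node(tree, ancestor)
  if (anc <= ntip) .stopf("ancestor must be an internal node")
  clade <- .tips_under(tree, anc)
  parent_of <- function(x) tree$edge[tree$edge[, 2] == x, 1]
  counts <- vapply(tips, function(tp) {
    if (!tp %in% clade) .stopf("tip '%s' is not in the clade of '%s'", tp, ancestor)
    nd <- .resolve_node(tree, tp)
    k <- 0L
    while (nd != anc) {
      nd <- parent_of(nd)
      k <- k + 1L
    }
    k
  }, 1L)
  data.frame(species = tips, node_count = as.integer(counts),
             stringsAsFactors = FALSE)
}

# One-sided (greater) Fisher exact p for a 2x2 table [[a, b], [c, d]]:
# hypergeometric upper tail over tables with fixed margins and first cell >= a.
.fisher_one_sided <- function(a, b, c, d) {
  m <- a + b          # row 1 total (family of interest)
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total (overlapping)
  hi <- min(m, k)
  sum(stats::dhyper(a:hi, m, n2, k))
}

#' One-sided enrichment of peak overlap in a focal ERV family
#'
#' Builds the 2x2 table (focal family vs other families) x (overlapping a
#' peak by >= `min_overlap_bp` vs not) over solo-LTRs and computes the
#' one-sided Fisher exact p (alternative: the focal family overlaps more) by
#' the hypergeometric tail, plus an odds ratio (Haldane 0.5 correction when a
#' zero cell exists).
#'
#' @param solos solo-LTR table with a `family` column.
#' @param peaks peak intervals (`scaffold`/`start`/`end`).
#' @param family_of_interest focal family label (e.g. `"ERVK"`).
#' @param min_overlap_bp minimum intersection in bp to count as overlapping
#'   (default 1).
#' @return list with `table` (2x2 matrix), `odds_ratio`, `p`, `degenerate`
#'   (TRUE when an overlap margin is empty).
#' @export
peak_overlap_enrichment <- function(solos, peaks, family_of_interest,
                                    min_overlap_bp = 1) {
  solos <- .solo_table(solos)
  if (is.null(solos$family)) .stopf("solos must carry a family column")
  .check_intervals(peaks, "peak set")
  if (!any(solos$family == family_of_interest)) {
    .stopf("no solo-LTRs of family '%s'", family_of_interest)
  }
  ov <- logical(nrow(solos))
  for (s in unique(solos$scaffold)) {
    si <- which(solos$scaffold == s)
    pk <- peaks[peaks$scaffold == s, , drop = FALSE]
    if (!nrow(pk)) next
    for (i in si) {
      inter <- pmin(solos$end[i], pk$end) - pmax(solos$start[i], pk$start)
      ov[i] <- any(inter >= min_overlap_bp)
    }
  }
  focal <- solos$family == family_of_interest
  a <- sum(focal & ov); b <- sum(focal & !ov)
  c_ <- sum(!focal & ov); d <- sum(!focal & !ov)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c(family_of_interest, "other"),
                                c("overlap", "no_overlap")))
  degenerate <- (a + c_) == 0 || (b + d) == 0
  if (degenerate) .warnf("degenerate 2x2 table: an overlap margin is empty")
  orv <- if (any(tab == 0)) ((a + .5) * (d + .5)) / ((b + .5) * (c_ + .5))
         else (a * d) / (b * c_)
  list(table = tab, odds_ratio = orv, p = .fisher_one_sided(a, b, c_, d),
       degenerate = degenerate)
}

#' Genes within flanking windows of qualifying elements
#'
#' A gene is assigned to window `w` iff the distance between the gene
#' interval and any element is at most `w` bp (overlap counts as distance 0).
#' Results are nested across increasing windows by construction.
#'
#' @param elements element intervals (`scaffold`/`start`/`end`).
#' @param genes gene intervals with a unique `gene_id` column.
#' @param windows window sizes in bp (default 2 kb / 5 kb / 10 kb).
#' @return list with `genes` (named list: window -> character vector of gene
#'   ids) and `counts` (data.frame `window`, `n_genes`).
#' @export
flanking_genes <- function(elements, genes, windows = c(2000, 5000, 10000)) {
  .check_intervals(elements, "element set")
  .check_intervals(genes, "gene set")
  if (is.null(genes$gene_id)) .stopf("genes must carry a gene_id column")
  if (anyDuplicated(genes$gene_id)) .stopf("gene_id values must be unique")
  windows <- sort(windows)
  mindist <- rep(Inf, nrow(genes))
  for (s in unique(genes$scaffold)) {
    gi <- which(genes$scaffold == s)
    el <- elements[elements$scaffold == s, , drop = FALSE]
    if (!nrow(el)) next
    for (i in gi) {
      gap <- pmax(0, pmax(genes$start[i], el$start) - pmin(genes$end[i], el$end))
      mindist[i] <- min(gap)
    }
  }
  sets <- lapply(windows, function(w) sort(genes$gene_id[mindist <= w]))
  names(sets) <- as.character(windows)
  list(genes = sets,
       counts = data.frame(window = windows,
                           n_genes = vapply(sets, length, 1L)))
}
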