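make_blocks <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(seq_along(rows), function(k) {
    r <- rows[[k]]
    data.frame(block_id = r$id, species = r$species, scaffold = "chr1",
               start = r$start, end = r$end, strand = "+", src_size = 100000,
               stringsAsFactors = FALSE)
  }))
}

test_that("sharing calls follow block coverage and clade membership", {
  solos <- data.frame(element_id = c("e1", "e2", "e3"), scaffold = "chr1",
                      start = c(100, 1000, 5000), end = c(300, 1200, 5200))
  blocks <- make_blocks(
    list(id = "b1", species = c("ref", "B"), start = c(900, 400), end = c(1300, 800)),
    list(id = "b2", species = "ref", start = 5000, end = 5200))
  calls <- classify_sharing(solos, blocks, "ref", c("ref", "B", "C"))
  expect_equal(calls$status, c("species_specific", "shared", "species_specific"))
  expect_equal(calls$shared_with[2], "B")
  expect_equal(calls$coverage[2], 1)

  # an alignment partner outside the clade does not make an element shared
  calls2 <- classify_sharing(solos, blocks, "ref", c("ref", "C"))
  expect_equal(calls2$status[2], "species_specific")

  expect_error(
    classify_sharing(solos, blocks, "ref", c("ref", "B"),
                     known_species = c("ref")),
    "unknown species")
})

test_that("sharing is monotone in the minimum overlap fraction", {
  solos <- data.frame(element_id = "e1", scaffold = "chr1", start = 0, end = 200)
  blocks <- make_blocks(
    list(id = "b1", species = c("ref", "B"), start = c(0, 0), end = c(120, 120)))
  st <- vapply(c(0.3, 0.6, 0.9), function(mo) {
    classify_sharing(solos, blocks, "ref", c("ref", "B"), min_overlap = mo)$status
  }, "")
  expect_equal(st, c("shared", "shared", "species_specific"))
})

test_that("ancestor attribution applies the two-child-clade parsimony rule", {
  tree <- "((A,B)ab,C)root;"
  calls <- data.frame(element_id = c("e1", "e2", "e3"),
                      status = c("shared", "shared", "species_specific"),
                      shared_with = c("B,C", "B", ""),
                      coverage = 1, stringsAsFactors = FALSE)
  out <- attribute_ancestor(calls, tree, "A", c("ab", "root"))
  expect_equal(out$ancestor_attribution, c("root", "ab", "none"))

  # sharing confined to the reference's own subclade cannot reach a deeper node
  calls2 <- data.frame(element_id = "e4", status = "shared", shared_with = "B",
                       coverage = 1, stringsAsFactors = FALSE)
  out2 <- attribute_ancestor(calls2, "(((A,B)ab,C)abc,D)root;", "A", c("abc", "root"))
  expect_equal(out2$ancestor_attribution, "none")

  expect_error(attribute_ancestor(calls, tree, "A", c("zz")), "unknown tree node")
  expect_error(attribute_ancestor(calls, "((A,B)ab,(C,D)cd)root;", "A", "cd"),
               "not on the path")
})

test_that("species-set truth is recovered perfectly at divergence 0", {
  cfg <- sim_config(genome_length = 80000, n_scaffolds = 1, ltr_length = 150,
                    divergence = 0, seed = 8)
  ss <- simulate_species_set("((A,B)ab,C)root;",
                             c(root = 10, ab = 10, A = 10, B = 5, C = 5),
                             cfg, seed = 9)
  solos <- ss$truth[ss$truth$species == "A", ]
  calls <- classify_sharing(solos, ss$blocks, "A", c("A", "B", "C"))
  calls <- attribute_ancestor(calls, ss$tree, "A", c("ab", "root"))
  merged <- merge(calls, solos[, c("element_id", "origin")], by = "element_id")
  expect_equal(nrow(merged), 30)
  expect_true(all(merged$status[merged$origin == "A"] == "species_specific"))
  expect_true(all(merged$status[merged$origin != "A"] == "shared"))
  expect_true(all(merged$ancestor_attribution[merged$origin == "ab"] == "ab"))
  expect_true(all(merged$ancestor_attribution[merged$origin == "root"] == "root"))
})

test_that("presence calls follow the breadth and depth thresholds", {
  solos <- data.frame(element_id = c("e1", "e2"), scaffold = "chr1",
                      start = c(10, 50), end = c(30, 70))
  cov_hi <- list(chr1 = rep(10L, 100))
  cov_zero <- list(chr1 = c(rep(10L, 50), rep(0L, 50)))
  pm <- call_presence(solos, list(i1 = cov_hi, i2 = cov_zero))
  expect_true(all(pm$present[, "i1"]))
  expect_equal(unname(pm$present[, "i2"]), c(TRUE, FALSE))
  expect_equal(unname(pm$breadth["e2", "i2"]), 0)
  expect_equal(unname(pm$mean_depth["e1", "i1"]), 10)

  expect_error(call_presence(solos, list(cov_hi)), "named list")
  expect_error(call_presence(solos, list(i1 = list(other = rep(1L, 10)))),
               "no track for scaffold")
})

test_that("population presence is recovered from simulated coverage", {
  sim <- small_sim(seed = 51, n_full = 0, n_solo = 60,
                   genome_length = 120000, n_scaffolds = 1)
  pop <- simulate_population(sim, 6, polymorphic_fraction = 0.2, depth = 20, seed = 5)
  pm <- call_presence(pop$solos, pop$coverage)
  expect_gte(mean(pm$present == pop$presence), 0.99)
})

test_that("intersection counts equal a brute-force pattern tally", {
  set.seed(52)
  m <- matrix(runif(200 * 10) < 0.6, 200, 10,
              dimnames = list(sprintf("e%03d", 1:200), sprintf("i%02d", 1:10)))
  got <- intersection_counts(m, min_size = 2)

  pats <- apply(m, 1, function(r) paste(colnames(m)[r], collapse = ","))
  counts <- integer(0)
  for (p in unique(pats)) {
    k <- 0
    for (q in pats) if (identical(p, q)) k <- k + 1
    counts[p] <- k
  }
  keep <- counts[counts >= 2]
  keep <- keep[order(-keep, names(keep))]
  expect_equal(got$patterns$individuals, names(keep))
  expect_equal(got$patterns$count, unname(keep))
  expect_lte(sum(got$patterns$count), nrow(m))
  poly <- sum(rowSums(m) > 0 & rowSums(m) < 10)
  expect_equal(got$polymorphic_count, poly)
  expect_equal(got$polymorphic_fraction, poly / 200)
})

test_that("degenerate presence patterns are reported correctly", {
  m <- matrix(TRUE, 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  got <- intersection_counts(m)
  expect_equal(got$patterns$individuals, "a,b,c")
  expect_equal(got$patterns$count, 5)
  expect_equal(got$polymorphic_fraction, 0)

  m2 <- matrix(c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE,
                 TRUE, TRUE, FALSE), 3, 3, byrow = TRUE,
               dimnames = list(NULL, c("i1", "i2", "i3")))
  got2 <- intersection_counts(m2)
  expect_equal(got2$patterns$individuals, "i1")
  expect_equal(got2$patterns$count, 2)
  expect_equal(got2$polymorphic_count, 3)
})

test_that("MAF blocks and coverage tracks round-trip through disk", {
  cfg <- sim_config(genome_length = 40000, n_scaffolds = 1, ltr_length = 150,
                    seed = 3)
  ss <- simulate_species_set("((A,B)ab,C)root;", c(root = 3, A = 2), cfg, seed = 4)
  maf <- tempfile(fileext = ".maf")
  write_maf(ss$blocks, maf)
  back <- read_maf(maf)
  expect_equal(back$species, ss$blocks$species)
  expect_equal(back$start, ss$blocks$start)
  expect_equal(back$end, ss$blocks$end)

  sim <- small_sim(seed = 53, n_full = 0, n_solo = 5,
                   genome_length = 30000, n_scaffolds = 2)
  pop <- simulate_population(sim, 2, polymorphic_fraction = 0.4, depth = 8, seed = 6)
  bg <- tempfile(fileext = ".bedgraph")
  write_coverage_bedgraph(pop$coverage$ind_01, bg)
  lens <- setNames(nchar(sim$genome), names(sim$genome))
  back2 <- read_coverage_bedgraph(bg, lens)
  expect_identical(lapply(back2, as.integer), lapply(pop$coverage$ind_01, as.integer))

  pm <- call_presence(pop$solos, pop$coverage)
  tsv <- tempfile(fileext = ".tsv")
  write_presence_tsv(pm, tsv)
  expect_equal(read_presence_tsv(tsv), pm$present)
})
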