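---
title: "Discovering and tracing solo-LTRs of endogenous retroviruses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and tracing solo-LTRs of endogenous retroviruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soloLTR)
```

## The biological problem

An endogenous retrovirus (ERV) integrates into a host germline as a provirus:
an internal *gag/pol/env* region flanked by two long terminal repeats (LTRs)
that are identical at the moment of integration, the whole element bracketed
by a short (4–6 bp) target-site duplication (TSD) of host sequence. Because
the two LTRs are near-identical direct repeats, unequal homologous
recombination between them excises the internal region together with one
LTR, leaving a *solo-LTR* — a single LTR still carrying the original TSDs.
The fraction of a genome's LTR content that exists in solo form (the
*formation ratio*, solo-LTR bp / total LTR bp) therefore measures how
efficiently a lineage purges proviral DNA, and the genomic distribution,
cross-species sharing and population polymorphism of solo-LTRs record the
history of retroviral activity.

`soloLTR` implements the complete desk-scale analysis: annotation of LTR
matches in an assembly, partition into intact pairs vs solo-LTRs, TSD
verification, formation statistics, cross-species sharing from
whole-genome-alignment blocks, presence/absence calls from population
coverage, and the statistical comparisons used downstream — all validated
against a simulator that plants elements with exact coordinate ground truth.

## The discovery pipeline

`solo_ltr_pipeline()` chains five stages, each also exposed on its own:

1. **Candidate intersection** (`intersect_candidates`). Two independent
   annotation sources each propose candidate LTR intervals; only their
   pairwise intersections with lengths in [100, 1000] bp are kept. The
   intersection interval itself (not either source's interval) is retained —
   the conservative reading when the two sources disagree on boundaries.
2. **Library construction** (`build_library`). Candidate sequences are
   clustered greedily, longest first, at 95% global-alignment identity; the
   retained representatives form the non-redundant LTR library. Identity is
   always matches / alignment columns, gaps counted, terminal gap columns
   excluded. Coverage of the shorter sequence is implicit in the end-to-end
   alignment of the shorter against the longer.
3. **Genome scan** (`scan_genome`). A seed-and-extend scanner: exact 11-mer
   seeds on both strands are clustered by alignment diagonal into candidate
   windows, each window is aligned locally against the query (match +1,
   mismatch −2, gap −5 to open and −2 to extend, computed by a compiled
   Gotoh kernel), and a hit is reported at ≥ 65% identity and ≥ 80% query
   coverage. Ranking uses the raw alignment score; no e-value statistics are
   computed, since a deterministic score ordering is reproducible and
   sufficient at this scale.
4. **Hit resolution** (`cluster_hits`, `filter_scaffolds`). Overlapping hits
   (single-linkage, ≥ 1 bp, strand-agnostic) collapse to the single best hit
   per cluster (score, then identity, then leftmost start), and hits on
   scaffolds shorter than 20 kb are discarded — on such scaffolds a pairing
   partner may be missing purely for assembly reasons.
5. **Pairing** (`pair_ltrs`). Hits on the same scaffold and strand with an
   inner gap (facing boundary distance) within 20 kb are candidate partners;
   partner affinity is global-alignment identity of the two hit sequences,
   thresholded at 85%. Pairs are mutual-best matches extracted greedily in
   descending identity, with best partners recomputed after every
   extraction; ties break by smaller inner gap, then smaller start
   coordinate. This recomputation resolves chains (A↔B mutual-best while C's
   best is B) deterministically and makes the result independent of input
   order. Everything unpaired is a solo-LTR.

Two readings of "within 20 kb" are possible; the package measures the inner
gap between facing boundaries by default and exposes `distance_mode =
"span"` for the outer-span reading. The same-strand requirement reflects
that proviral LTRs are direct repeats; opposite-strand near-duplicates are
never legitimate partners. Whether "best" should mean identity or alignment
score is not dictated by the method's 85% threshold being stated in identity
units only; identity is used, so the threshold and the ranking live on the
same scale.

TSD verification (`verify_tsd`) extracts 10 bp (optionally 15 or 20 bp)
immediately outside each element boundary — for a pair, upstream of the left
LTR and downstream of the right — and passes iff some 4–6 bp motif occurs
*exactly* in both flanks, reporting the longest such motif, leftmost on
ties. Mismatch-tolerant matching is deliberately not offered: the element
removal process degrades TSDs over time, and that imperfection is probed by
widening the flank window rather than by loosening the match.

## The simulator and what it does (not) emulate

`simulate_genome()` plants full proviruses (TSD + LTR + internal + LTR +
TSD) and solo-LTRs (TSD + LTR + TSD) in i.i.d. uniform ACGT background, at
rejection-sampled positions that keep elements ≥ 100 bp apart and away from
scaffold edges. Substitutions are Jukes–Cantor point mutations; there are no
indels, so truth coordinates stay exact. Two divergence clocks are separated
deliberately:

* `insertion_divergence` (default 0.15) separates each insertion event from
  its family master. Independent insertions of one ERV family are never
  identical in a real genome — repeat families are conventionally delimited
  at roughly 80% internal identity — and this is precisely why an 85%
  pairing threshold can distinguish the two LTRs of one provirus from two
  unrelated insertions of the same family. A simulator without
  between-insertion divergence would make that separation impossible at low
  element age, which is a property of no real genome.
* `divergence` (default 0) is the post-insertion age: each LTR copy is
  mutated independently at this rate, so an intact provirus's two LTRs drift
  apart at twice the per-copy rate, exactly as LTR–LTR dating assumes.

`simulate_recombination()` performs the deletion the pipeline is designed to
detect — internal region plus one LTR removed in place (the left genomic
copy is retained by convention; which copy survives recombination is
unidentifiable anyway), TSDs untouched, downstream truth coordinates
shifted. `simulate_population()` draws per-individual presence (polymorphic
elements are re-drawn until at least one carrier and one non-carrier exist)
and per-position Poisson coverage, zeroed across absent elements.
`simulate_species_set()` plants elements on branches of a species tree over
a shared ancestral background, so orthologous coordinates — and hence MAF
alignment blocks — come from exact bookkeeping rather than from an aligner.

The simulator does **not** emulate: isochore or repeat-rich background
composition, indels, nested or fragmented elements (nesting is off by
default), proviral open reading frames, or read-level sequencing artefacts
(coverage tracks are generated directly). Passing tests therefore
demonstrate correctness of the method's logic under clean conditions, not
robustness to every artefact of real assemblies; the divergence sweeps are
the sensitivity analysis the simulator *can* support.

## Tracing sharing, ancestry and polymorphism

`classify_sharing()` marks a solo-LTR *shared* when at least half of its
interval (tunable `min_overlap`; the method description gives no fraction)
is covered by alignment blocks containing another clade species.
`attribute_ancestor()` assigns a shared element to the **oldest** listed
ancestor node whose presence pattern — the reference tip plus all
`shared_with` species — spans at least two of the node's child clades:
presence in two daughter lineages is the parsimony condition for the
insertion predating the node. The reference tip itself counts as presence in
its own child clade; without this, an element shared only with the
reference's sister species could never be attributed to their common
ancestor, which the pattern plainly implies.

`call_presence()` declares an element present in an individual when ≥ 80% of
its positions have depth ≥ 2. Both thresholds are package defaults (the
coverage-as-indicator rule has no canonical cutoffs) and are exposed as
arguments; absence is purely coverage-defined, so deletion alleles and
reference-assembly gaps are not distinguished. `intersection_counts()`
tallies exact presence patterns (UpSet distinct mode), reporting patterns of
size ≥ 2 plus the polymorphic count and fraction.

## Statistical primitives

`welch_t()` (unequal-variance t with Welch–Satterthwaite degrees of
freedom), `pearson_ci()` (product-moment r, Fisher-z 95% CI, t-based p),
`speciation_depth()` (internal nodes from a named ancestor, inclusive, to a
tip, exclusive — the ancestor-inclusive convention only shifts all counts by
a constant and cancels in any correlation), `peak_overlap_enrichment()`
(one-sided Fisher exact p by the hypergeometric tail, Haldane-corrected odds
ratio when a cell is zero), and `flanking_genes()` (2/5/10 kb windows,
overlap counting as distance zero, nested by construction). The direction of
every one-sided test is the caller's explicit choice; nothing is inferred
from the data. No multiple-testing correction is applied inside these
primitives. All are checked against independent reference implementations
(`t.test`, `cor.test`, `fisher.test`) and, for the Fisher tail, against full
margin-fixed enumeration.

## Numerical and validation choices

* All coordinates are 0-based half-open (BED convention), in memory and on
  disk; conversion to 1-based happens only at Biostrings/IRanges call sites.
* The alignment kernel is exact Gotoh dynamic programming (no banding or
  X-drop heuristics); the seed stage is the only heuristic in the scanner,
  and at 11 bp seeds a 65%-identity hit is seeded with overwhelming
  probability.
* Seeded runs are bit-reproducible (`set.seed` with Mersenne–Twister and
  rejection sampling pinned explicitly).
* The validation suite exercises: a 500 kb genome with 30 proviruses and 30
  solo-LTRs (perfect recovery and exact formation-ratio arithmetic at
  divergence 0); ten replicate 120 kb genomes at divergences 0/0.05/0.10
  (accuracy ≥ 95% at 0.05, monotone degradation); 200 randomized pairing
  instances against exhaustive mutual-best enumeration; TSD recovery for all
  planted lengths with a 1000-trial shuffled-flank null (~17% false-positive
  rate at 4 bp motifs, comfortably under 30%); a three-species tree with 50
  elements per branch (perfect sharing and attribution at divergence 0); and
  a 500-element × 19-individual population at depth 20 (≥ 99% presence-call
  agreement). These sizes were chosen so the whole suite runs comfortably on
  a laptop while every stage is still exercised at non-trivial scale.

## Known limitations

Tandem or nested insertions are not resolved by the single-linkage hit
clustering (the best hit wins the whole cluster); heavily fragmented
assemblies are handled only by the blunt 20 kb scaffold filter; identity is
computed from a single optimal alignment, so co-optimal alignments with
different match counts could in principle flip a decision within ~1% of a
threshold; and the sharing classifier trusts the alignment blocks it is
given — misalignment in the upstream whole-genome alignment propagates
directly into sharing calls.
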