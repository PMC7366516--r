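---
title: "Inferring phylogeny from chromosome rearrangement characters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring phylogeny from chromosome rearrangement characters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyotree)
library(dplyr)
```

## The problem

Comparative chromosome painting (ZOO-FISH) hybridizes whole-chromosome
probes from a reference species — typically the chicken, *Gallus gallus*
(GGA) — onto the metaphases of a target species, revealing which
descendant chromosomes carry material homologous to each ancestral
chromosome. In groups with heavily reshuffled karyotypes, such as
parrots (Psittaciformes), the pattern of interchromosomal rearrangements
(fusions and fissions) accumulated since the common ancestor is itself a
source of phylogenetic characters: a shared syntenic association like
GGA8/GGA9 on a single chromosome is a derived state that can unite
clades.

karyotree implements this workflow end to end:

1. **homology maps** — tidy, parseable transcriptions of painting
   results (one row per ancestral-segment-to-descendant-chromosome
   assignment);
2. **event detection** — fusions (descendant chromosomes bearing two or
   more ancestral homologies) and fissions (ancestral chromosomes spread
   over two or more descendants);
3. **binary character coding** — a presence/absence/missing matrix over
   taxa;
4. **maximum parsimony inference** — exhaustive or TBR heuristic search,
   Fitch counting, bootstrap supports, consensus trees, CI/HI/RI;
5. **simulation** — a karyotype evolution generator that produces
   homology maps with known history, so every stage can be validated
   against ground truth.

## Nomenclature: PAK versus GGA

Rearrangements are described against the Putative Avian Ancestral
Karyotype (PAK, 2n = 80). PAK1–11 and PAK13–15 correspond to GGA1–GGA3,
GGA4q, GGA5–GGA9, GGA4p, GGA10 and GGA12–GGA14; PAK12 is GGA11. The two
arms of chicken chromosome 4 are *separate* ancestral chromosomes (the
chicken itself carries a derived PAK4/PAK10 fusion). This has two
consequences baked into the package:

- **event detection** (`detect_fusions()`, `detect_fissions()`) works at
  the whole-chromosome level of the map's own labels, because published
  event inventories are stated that way ("GGA3/GGA4 in MMO7");
- **character coding** first converts to PAK units, where GGA4q and
  GGA4p are distinct, so that associations such as PAK1/PAK4
  (GGA1p/GGA4q) — the character uniting the macaws — are expressible.

Unidentified microchromosome homologies (written `micro`) are carried
through parsing and detection but never become characters: they cannot
be matched across taxa.

## Character coding rules

Two kinds of characters are coded automatically from a set of homology
maps; both definitions are *membership predicates* that any map can be
tested against:

- A **fusion association** is the full set of ancestral chromosomes
  observed together on one descendant chromosome in at least one taxon
  (a triple fusion is one character, not three pairs; a `pairwise`
  switch decomposes them for sensitivity analysis). A taxon scores 1
  when some descendant chromosome carries *all* participants — possibly
  among others. This containment rule means a lineage that inherited
  the association and then fused further material still scores 1, which
  is what makes character states correspond to clades on simulated
  homoplasy-free histories.
- A **fission pattern** (A, k) is present when ancestral chromosome A is
  distributed over at least k descendant chromosomes, one character per
  distinct observed k ≥ 2. The cumulative (">= k") reading, rather than
  "exactly k", has the same motivation: a tip whose ancestor passed
  through the 2-piece state on the way to 4 pieces should not score 0
  for the 2-piece character.

A taxon scores `?` (missing) for any character one of whose chromosomes
has no assignment in that taxon's map — the outgroup situation for
characters involving chromosomes never assayed in a given species.
Inversions are qualitatively detectable with finer probe sets but not
codable from whole-chromosome maps; they can be supplied as manual
`other-discrete` columns.

A binary character is **parsimony-informative** when each state is
present in at least two taxa (missing excluded); variable but not
informative characters are autapomorphies.

## The parsimony engine

Tree lengths are Fitch counts (unordered binary characters, `?` as the
full state set at the leaf), computed by a small C++ kernel over a
postorder encoding of each topology; the count is independent of
rooting. Two searches are provided:

- `exhaustive_search()` enumerates all (2n−5)!! unrooted binary
  topologies (10,395 at n = 8 — well under a second) and is exact; it
  refuses above `max_taxa = 10`.
- `heuristic_search()` performs random-addition-sequence stepwise
  addition followed by TBR branch swapping. Each replicate keeps a
  *pool* of all equally parsimonious trees and swaps on every pool
  member until the neighborhood is exhausted (the MULTREES behaviour of
  classic parsimony software), so tied optima and multiple islands
  reachable through plateaus are retained. Defaults: 10 addition
  replicates, unlimited pool (a safety cap of 2000 exists), zero-length
  branches not collapsed. Ties in stepwise addition break toward the
  earliest insertion edge under the seeded addition order, never by
  ambient hash order, so runs are reproducible bit for bit.

`bootstrap()` resamples characters with replacement to the original
count; each replicate is analysed with the configured search
(exhaustive by default up to 10 taxa — exact and, at these sizes, about
as fast as swapping) and contributes the clades of its strict consensus
of MP trees, a deterministic summary of the replicate. Support is the
percentage of replicates containing the clade; the majority-rule
bootstrap consensus carries supports as node labels.

Fit statistics follow the standard ensemble definitions: CI = Σm/L
(m = 1 for each character variable over observed states), HI = 1 − CI,
RI = (ΣM − L)/(ΣM − Σm) with M the star-tree (minority-state) length,
reported as `NA` when ΣM = Σm. L = 0 yields CI = 1 by convention, with
a message.

`strict_consensus()`/`majority_rule()` are built from bipartition sets
(ape's `consensus()` serves as an independent cross-check in the test
suite, as do phangorn's `parsimony()` and `RF.dist()` for the Fitch
kernel and `robinson_foulds()`).

## The simulator

`simulate_karyotypes()` evolves a genome — a list of chromosomes, each
an ordered run of segments labelled by ancestral chromosome — down a
user-supplied rooted tree. Per branch, each event type occurs
Poisson(rate × length) times: fusions concatenate two chromosomes
(tandem; centric versus tandem is not distinguishable by painting and
not modelled), fissions cut at a segment boundary, inversions flip a
contiguous run in place. Defaults are fusion 0.5, fission 0.5,
inversion 0.25 per unit branch length; there are no published
quantitative rates, so these were chosen once so that trees with a few
tens of units of total length yield matrices of roughly the size real
painting studies produce (about 30 characters), with fusions frequent
enough to drive the diploid number down as observed in derived
karyotypes.

Modelling choices worth knowing:

- The ancestral template (PAK-like, 15 macro + 25 micro pairs, 2n = 80)
  is pre-segmented — macros into 6 segments, micros into 2 — because the
  fission move is defined only at segment boundaries; an unsegmented
  chromosome could never split.
- With `allow_breakpoint_reuse = FALSE` (default) breakpoint bookkeeping
  is global across the whole tree: a template boundary is cut at most
  once anywhere, fusion junctions are never re-cut, and no pair of
  ancestral chromosomes fuses twice independently. Under these rules
  every event survives to all tips below it, so the event log's implied
  character matrix (`truth_matrix()`) is homoplasy-free on the true
  tree (CI = 1), and tip diploid numbers obey
  2n = 80 − 2·fusions + 2·fissions along each root-to-tip path.
- Inversions change only within-chromosome segment order, so they are
  invisible in the emitted homology maps — mirroring the limitation of
  real whole-chromosome painting.
- Homology maps report whole-chromosome membership only; arm-level
  positions of the simulated segments are not emitted.

Event detection on simulated tips exactly reproduces the event log when
events do not interact. Two interactions are possible even without
breakpoint reuse, and the test suite conditions on their absence where
exact correspondence is asserted: stacked fusions on one branch hide
the intermediate association (the union is observed, the intermediate
set never surfaces), and fissions of the same chromosome on disjoint
lineages make the cumulative fission count non-identifiable as a single
clade character. At low-to-moderate event densities both are rare; the
helper predicate `events_interaction_free()` in the test suite
formalises the condition.

What passing simulation tests does *not* show about real data: the
generator emits complete, error-free maps with every chromosome
assigned in every taxon. Real painting data have missing assignments
(scored `?`), unidentified microchromosomes, arm-level ambiguity and
occasional conflicting table entries — which is why the packaged
transcriptions carry a provenance column and the fixture README lists
every transcription decision.

## Study conditions used by the heavier checks

- **Oracle equivalence**: 50 random 8-taxon binary matrices of 20–40
  characters; the heuristic search (10 addition replicates) must attain
  the exhaustive optimum length on all and recover the identical MP
  tree set in at least 49.
- **Fitch correctness**: 200 random (tree, column) instances with up to
  7 leaves against brute-force enumeration of all internal state
  assignments.
- **Tree recovery**: the fixed balanced 8-taxon tree of
  `sim_study_tree()` with internal branches of length 5 and pendant
  branches of length 2. At the default rates an internal edge expects
  about five coded events (at least three was the design floor), so the
  probability that some internal edge receives no event at all is about
  3 percent per run; the strict consensus of the exact MP trees must
  equal the true tree in at least 90 of 100 seeded runs.
- **Bootstrap**: replicate counts of 1000 for reported supports; the
  analytic binomial bound (a split supported by every informative
  character is missed only when the resample draws none of them) is the
  oracle for the clean-matrix case.

These problem sizes keep the full suite to a few minutes while leaving
each check statistically meaningful.

## The reconstructed demonstration matrix

The published analysis this package's fixtures transcribe used a
34-character supplementary matrix that is not printed in the article
body; only the syntenic-group table (here `table5_all_species.tsv`) and
the named associations are. The packaged
`matrix_reconstructed_synthetic.nex` is therefore *our own auto-coding*
of that table for the six Neotropical species plus the chicken identity
row and a synthetic conserved-karyotype outgroup row for *Turdus*
(`turdus_synthetic.tsv`) — 17 characters, of which 8 are
parsimony-informative. It is labelled synthetic, used for smoke tests
and report-only summaries, and its statistics are not expected to equal
the published ones (the original matrix additionally encoded BAC-level
microchromosome fusions and inversion characters that cannot be
recovered from the printed tables).

```{r study, eval = FALSE}
maps <- bind_rows(
  parse_homology_tsv(karyotree_example("table5_all_species.tsv")),
  parse_homology_tsv(karyotree_example("turdus_synthetic.tsv"))
) |>
  filter(taxon %in% c("AHY", "ACH", "PFR", "AMA", "MMO", "AAE", "GGA", "TRU"))

m <- build_matrix(maps)
res <- exhaustive_search(m)
glance(res)
boots <- bootstrap(m, replicates = 1000, seed = 1)
root_on_outgroup(strict_consensus(res$mp_trees), c("GGA", "TRU"))
```

## Degenerate inputs and numerical corners

- Empty homology tables (header only) parse to an empty map with a
  warning; duplicate assignments, odd diploid numbers and unknown
  region tokens are errors naming the offending line.
- Matrices with two taxa are accepted for coding (with a warning) but
  refuse tree search; `exhaustive_search()` needs three taxa,
  `heuristic_search()` four.
- A character column with no observed state is rejected at
  construction.
- Bootstrap on a matrix without informative characters runs but is
  flagged `degenerate`.
- `root_on_outgroup()` falls back to the best-matching edge, with a
  warning, when the outgroup is not monophyletic.
- Fission proposals that find no eligible boundary resample another
  chromosome and are logged as skipped when nothing is cuttable.

## Known limitations

- Characters are binary and unordered; no weighting, no Dollo or
  ordered variants (the workflow this reimplements used none).
- Event detection cannot see intrachromosomal rearrangements, so
  inversion-rich histories are underestimated by design.
- The heuristic search is a hill climber: on pathological matrices an
  equally parsimonious island not connected to any addition-sequence
  basin through equal-length TBR moves can be missed, which is why the
  exhaustive search is the default at 10 taxa or fewer.
- `exhaustive_search()` at its `max_taxa` ceiling of 10 evaluates about
  two million topologies, which takes minutes, not seconds.
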