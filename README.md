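# karyotree

Phylogenetic inference from chromosome rearrangement characters.

Comparative chromosome painting maps whole-chromosome probes of a
reference species (usually the chicken, *Gallus gallus*, GGA) onto the
karyotype of a target species, revealing which descendant chromosomes
carry each ancestral chromosome's material. In birds with heavily
reorganised karyotypes — parrots being the classic case — the fusions
and fissions this uncovers are heritable, discrete and scorable across
species, so they can be coded as binary characters and analysed by
maximum parsimony. karyotree implements that entire workflow:

- **Homology maps**: a tidy TSV dialect for painting results (one row
  per ancestral-to-descendant assignment, PAK/GGA nomenclature with the
  fixed PAK1–15 ↔ GGA1–14 conversion), with validation, round-trip
  serialization and packaged transcriptions of published parrot tables.
- **Event detection**: `detect_fusions()` (descendant chromosomes
  carrying ≥ 2 ancestral homologies, i.e. syntenic associations) and
  `detect_fissions()` (ancestral chromosomes spread over ≥ 2
  descendants).
- **Character coding**: `build_matrix()` turns a set of maps into a
  taxa × characters grid over {0, 1, ?}; fusion-association characters
  use full participant sets with containment scoring, fission patterns
  are cumulative (chromosome split into ≥ k pieces); NEXUS and PHYLIP
  I/O.
- **Maximum parsimony**: Fitch lengths (C++ kernel), exact
  `exhaustive_search()` over all (2n−5)!! topologies, PAUP-style
  `heuristic_search()` (random addition sequences + TBR branch swapping
  with a pool of equally parsimonious trees), `bootstrap()` with
  per-replicate strict consensus, `strict_consensus()` /
  `majority_rule()`, outgroup rooting, Robinson–Foulds distances, and
  ensemble CI / HI / RI.
- **Simulation**: `simulate_karyotypes()` evolves fusion / fission /
  inversion events along a known tree from a PAK-like 2n = 80 ancestor
  and emits homology maps, the true character matrix and a replayable
  event log — ground truth for end-to-end validation.

Results are tibble-first (`tidy()`, `glance()`, `autoplot()` methods on
matrices, search results and bootstrap objects); trees are `ape::phylo`.

## Worked example

Code the packaged syntenic-group table (six Neotropical parrots, the
chicken identity row and a synthetic *Turdus* outgroup row) and analyse
it:

```r
library(karyotree)
library(dplyr)

maps <- bind_rows(
  parse_homology_tsv(karyotree_example("table5_all_species.tsv")),
  parse_homology_tsv(karyotree_example("turdus_synthetic.tsv"))
) |>
  filter(taxon %in% c("AHY", "ACH", "PFR", "AMA", "MMO", "AAE", "GGA", "TRU"))

m <- build_matrix(maps)
m
#> <char_matrix> 8 taxa x 17 binary characters
#>   autapomorphic/uninformative: 9, parsimony-informative: 8
#>   taxa: GGA, AHY, ACH, PFR, AMA, MMO, AAE, TRU

res <- exhaustive_search(m)
res
#> <parsimony_search> (exhaustive)
#>   4 most parsimonious tree(s), length 21
#>   CI = 0.8095, HI = 0.1905, RI = 0.6923

boots <- bootstrap(m, replicates = 1000, seed = 1)
clade_support(boots, c("AHY", "ACH", "PFR", "AMA", "MMO", "AAE"))
#> [1] 83.3
```

The matrix has 17 auto-codable characters, 8 of them
parsimony-informative; the four most parsimonious trees need 21 steps
(CI 0.81 — some homoplasy, largely from convergent fission counts), and
parrot monophyly against the two outgroups gets 83% bootstrap support.
Event detection on the *M. monachus* painting table reproduces the
published inventory — for example the GGA1/GGA2 association on MMO3 and
GGA8/GGA9 on MMO8:

```r
mmo <- parse_homology_tsv(karyotree_example("tables2_mmo.tsv"))
detect_fusions(mmo)
#> # A tibble: 7 x 5   (MMO1, MMO3, MMO7, MMO8, MMO9, MMO10, MMO13)
count_descendant_pairs(mmo, "GGA1")
#> [1] 4
```

Note the packaged matrix is a *reconstruction* auto-coded from the
printed tables (the original study's supplementary matrix, with its
additional BAC and inversion characters, is not part of the fixtures),
so its statistics describe this reconstruction, not the published run;
see the methods vignette (`vignettes/karyotree-methods.Rmd`).

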