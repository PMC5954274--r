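---
title: "Resolution effects in synteny-block ancestral reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolution effects: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, conventions and
design choices. Code chunks are illustrative and not evaluated at build
time; every empirical statement made here is one the test suite or the
acceptance script computes.

## The analysis in one paragraph

Three genomes, represented as linear chromosomes of signed synteny blocks,
are compared at a series of resolution levels `L`. At each level, blocks
with fewer than `L` genes are ignored and surviving neighbours that are
close on all three genomes are merged. The median genome — minimizing the
summed DCJ distance to the three inputs — is recomputed at every level,
together with breakpoint distances, optimal rearrangement scenarios
decomposed by operation type, the breakpoint-reuse statistic `r = 2d/b`,
and a conserved-synteny estimate of translocation counts. Comparing levels
shows how resolution loss blurs the differences between the genomes.

## Genomes, blocks and formats

A genome (`block_genome`) is an unordered set of linear chromosomes, each
an ordered sequence of signed block identifiers; a chromosome equals its
reverse complement. Circular chromosomes are rejected at parse time: the
intended domain is plant nuclear genomes. Text I/O uses the GRIMM/UniMoG
convention (`>name`, signed integers, `$` terminators), the de facto
standard of block-order rearrangement tools.

Block tables store one row per homologous block with an ancestral colour
label (1–21, the post-triplication core-eudicot chromosomes) and, per
genome, a scaffold, a gene-index span, a strand and a gene count. All
coordinates are **1-based inclusive gene indices** — ordinal positions of
genes on their scaffold — never base pairs, because every rule in the
analysis (the level threshold, the 250-gene merge cutoff) counts genes.
Gene counts may be smaller than the span: fractionation erodes block ends.

## Three-way blocks

Two pairwise tables sharing the pivot genome are intersected along the
pivot. Where a pivot interval is covered by one record from each table,
the intersection becomes a three-way block; partial overlaps are split at
the interior boundaries. Counterpart intervals in the non-pivot genomes
are split at the same boundaries by **linear mapping of the cut offsets,
rounding toward the interior** (trims round up). Ceiling rounding is not
cosmetic: it guarantees that sibling sub-blocks of one parent map to
disjoint counterpart intervals, so the extracted genomes are always valid.
A piece whose counterpart span collapses under rounding is dropped, as is
any overlap whose parents disagree on colour (both with a message). The
third pairwise table is used only for consistency checking; the package
never re-splits against it by default.

Because three-way construction only ever merges blocks across junctions
conserved in *all* genomes, and only ever splits blocks at boundaries
present in *both* genomes of a pair, it preserves every pairwise DCJ
distance exactly. The test suite verifies this against the simulator's
ground truth.

The informativeness filter keeps a pivot scaffold only if it carries at
least two successive blocks whose counterparts are not successive — not
adjacent, or adjacent with a different extremity adjacency (inconsistent
relative orientation) — in at least one other genome. "Successive" is
order-based (adjacent among the scaffold's blocks), not distance-based.
Whether real informative scaffolds are also long is treated as a
consequence, not a filter.

## The resolution engine

* **Level filter.** A block's size is the *minimum* of its per-genome gene
  counts (configurable to mean/max). The minimum is the conservative
  choice under fractionation, which systematically erodes counts
  differently per lineage. `L = 0` keeps everything.
* **Merging.** Two retained records merge when, on every genome, they are
  adjacent among retained records with an inter-block gap strictly below
  250 genes, measured in gene indices — so genes of deleted blocks (and
  genes never in blocks) between them are automatically counted — and
  share a colour. The cutoff is strict: a 249-gene separation merges, 250
  does not.
* **Order consistency.** The two parts must read in the same order on
  every genome, up to reversal of the whole pair: the occurrence is
  normalized to read `first-then-second`, flipping both strands when the
  physical order is reversed. If one genome flips *both* parts relative to
  another the pair is order-inconsistent and never merges. If exactly one
  part's polarity disagrees, the merger proceeds with
  `polarity_determinate = FALSE` and the odd genome is recorded — one
  binary orientation choice per indeterminate block.
* **Scan order.** Candidate pairs are scanned left-to-right along the
  pivot genome and merging is repeated to a fixpoint, with ties broken by
  block id. Whether a single pass or transitive closure was intended by
  the procedure the engine follows is genuinely open; the fixpoint is the
  deterministic choice and is documented as such.
* **Polarity resolution.** The indeterminate orientation bits are set by a
  first-improvement local search: scan blocks in id order, flip one sign,
  keep the flip if the objective — the DCJ median total score of the three
  genomes — strictly improves; repeat full passes until none improves
  (at most 20 passes as a safety valve; the integer objective guarantees
  termination well before that). The search is deterministic.

The level report tabulates blocks deleted/remaining/after-mergers and gene
content; `genes_not_included + genes_remaining` is invariant across levels
(only block genes are counted; unaligned gap genes are outside the
accounting, matching how block tables are reported in practice).

## Distances, scenarios, reuse

Extremity encoding is standard: block `b` has a tail and a head; genome
adjacencies form an involution with explicit telomeres. DCJ distance is
`N − (C + I/2)` with `C` cycles and `I` odd paths of the two-genome
adjacency graph. Breakpoint distance uses the multichromosomal convention
`b = N − a − e/2`, crediting shared telomeres one half, which is exactly
the convention under which `r = 2d/b` spans `[1, 2]`: 1 when every
operation created two new breakpoints, approaching 2 for mutually
randomized genomes. Both bounds are exercised by the acceptance tests on
hundreds of random pairs.

Sorting scenarios are built greedily: candidate operations are derived
from target adjacencies and telomeres absent from the current genome; each
candidate must reduce the distance by exactly one and keep every
chromosome linear (circular intermediates are forbidden; for linear
genomes a linear-safe distance-reducing operation always exists). Among
candidates, the prioritized type — translocations or reversals — is taken
first, with deterministic tie-breaking by lowest extremity pair.
Operations are classified by the chromosomes of their two cuts and the
change in chromosome count: same chromosome, count unchanged → reversal;
two chromosomes, count unchanged → translocation; count −1 → fusion;
count +1 → fission. Running both priority modes brackets the attainable
type counts for the greedy family of scenarios.

When a greedy chain dead-ends, the search backtracks over the complete
operation neighbourhood, so a returned scenario of length `d` is optimal
and a failure is a proof. A small fraction of genome pairs — those whose
remaining differences form unoriented components confined to single
chromosomes — admit **no** optimal linear-safe scenario at all: sorting
them without circular intermediates necessarily costs extra steps. For
such pairs one distance-neutral unlocking reversal is inserted per
component and a warning reports that the scenario length exceeds the DCJ
distance. Likewise, the priority bracketing is a property of the greedy
scheme, not a theorem: rare instances can invert it.

## The DCJ median

The median solver is a from-scratch adjacency branch-and-bound:

* **Shared-adjacency reduction.** An adjacency present in at least two of
  the three genomes is a 2-cycle of the multiple breakpoint graph — an
  adequate subgraph — and is fixed in the median. The analogous rule is
  **not** applied to telomeres: caps of different genomes are distinct
  vertices, no 2-cycle forms, and instances exist where every optimal
  median pairs an extremity that is telomeric in two genomes. (This was
  caught by the brute-force validation suite during development.)
* **Component decomposition.** The remaining free extremities decompose
  into connected components of the breakpoint graph; each is solved
  exactly, with the same 2-cycle rule applied recursively inside the
  search (score mode only), candidates ordered by immediate cycle gain,
  and a per-genome admissible bound: a fragment with both ends open can
  contribute at most one cycle, a one-open-ended fragment at most half,
  and only when its parity can come out even.
* **Linearity.** The median is defined over linear genomes. When every
  combination of per-component optima would close a circular chromosome,
  near-optimal component assignments are admitted under a growing total
  loss budget (iterative deepening in half-unit steps); any cycle can be
  broken by replacing one of its adjacencies — necessarily internal to a
  single component — by telomeres, so the relaxation always terminates in
  practice. Configurations that would require two or more completely
  unsupported adjacencies *between* components are outside the search
  space; exhaustive 4-block validation found no instance needing them.
* **Anytime behaviour.** A node budget (default 200,000) caps worst-case
  work; if exhausted, the best linear median found is returned, its score
  recomputed from the realized genome, with `exact = FALSE` and a warning.
  All correctness tests run far below the budget.
* **Enumeration.** With `enumerate_all = TRUE` the solver returns every
  distinct optimal median (canonical form: chromosomes oriented so the
  smaller-magnitude end block leads positively, sorted by leading block),
  up to a cap of 50,000, within the shared-adjacency-reduced space.
  Median counts are representation-sensitive, so counts are only ever
  compared against this package's own canonical form.

The total score is always sandwiched between
`ceiling((d(A,B)+d(A,C)+d(B,C))/2)` and the best input genome's summed
distance, and the solver is validated against exhaustive minimization over
all linear genomes on four blocks.

Random, phylogenetically unrelated triples are the hard regime for any
exact median solver; the design targets related genomes, where shared
adjacencies collapse most of the instance.

The breakpoint median maximizes total adjacency weight (number of genomes
containing each candidate adjacency, telomeric states credited one half,
folded into edge weights) by an exact component-wise branch-and-bound
matching; cycles forced by the matching are broken at their lightest edge
with a message. The matching weight is validated against brute force.

## The translocation estimator

With `c^(i)` the number of genome-A chromosomes contributing at least one
fragment to B-chromosome `i`, `S = Σ c^(i)`, and length fractions `p`,
`q`, three moment equations are exposed: the equal-chromosome-number form
(`eq5`), the general form (`eq6`), and the near-equal-length closed form
(`eq7`): `1 − S/(cd) = (1 − 1/d)^(1 + 2t̂/c)`. `eq5`/`eq6` are solved by
bisection (monotone right-hand side, bracket `[0, 50cd]`, tolerance 1e-9 —
the solver and tolerance are this package's choices). `eq5` is documented
as equal-`c`-and-`d` only and errors otherwise. Negative closed-form
results are clamped to zero with a warning; `S ≥ cd` (complete mixing) and
`d = 1` are errors.

Omitting the factor 2 (appropriate for high-reuse comparisons, where a
translocation effectively marks one chromosome rather than two) exactly
doubles the `eq7` estimate: it rescales trends but is *not* a consistent
estimator of `t`. The recovery experiment therefore defaults to the
factor-2 model; at `c = d = 8`, `t = 5`, it recovers the truth to within a
few percent on average, degrades into systematic underestimation as `t`
approaches `c^2` (second-order exchanges are neglected by the model), and
is exactly zero at `t = 0`. When applied inside the pipeline,
chromosome-length fractions use summed block gene counts — the only
length measure block-level data carries.

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed once:

* **Ancestor:** 204 blocks on 21 chromosomes, one colour per chromosome —
  the post-triplication core-eudicot regime. Block gene counts are
  lognormal around a median of 60, clamped to [5, 600] (`sdlog =
  log(max/median)/3`), giving ≈15k genes in blocks: the scale of a real
  three-way block set. The minimum of 5 genes is the conventional
  synteny-detection floor.
* **Unaligned gaps:** neighbouring blocks are separated by runs of
  unaligned genes, lognormal (median 30, `sdlog` 1.2). A junction
  inherited from the ancestor keeps one shared gap size in every genome;
  junctions created by rearrangement draw fresh per-genome gaps. The
  emulated aligner chains neighbours into one maximal pairwise block only
  when the gap is at most 20 genes in both genomes — the granularity of
  real block tables comes from this interplay, and the 250-gene merge rule
  operates above the chaining scale.
* **Branches:** the pivot leaf is fast and translocation-rich (24
  operations; mix 0.35/0.55/0.05/0.05 reversal/translocation/fusion/
  fission; fine-scale segments, geometric mean 2 blocks; translocations
  may exchange an empty tail, i.e. move a terminal segment); the sister is
  conservative (6 operations, reversal/fusion dominated); the outgroup
  intermediate (12 operations). Operation counts are scaled down from
  deep-time plant divergences so that exact medians remain routine; the
  qualitative asymmetry — one fast, translocation-rich leaf against a
  conservative sister — is the condition the analysis is designed to
  expose.
* **Noise:** each leaf relocates a few small blocks (12/1/3 for
  pivot/sister/outgroup) to random positions, emulating out-paralog
  misassignment and assembly noise. Ortholog/out-paralog separation is
  deliberately absorbed into these generator assumptions rather than
  modelled at the sequence level. These blocks inflate apparent distance
  at full resolution and drop out of the analysis once `L` exceeds their
  gene count — they are the concrete mechanism behind the blurring effect
  at the heart of the analysis.
* **Fractionation:** per genome, each block loses `Poisson(2)` genes at
  each end (floor of one gene).
* **Scaffolds:** the pivot assembly is fragmented into ~30 scaffolds at
  random block boundaries; fragmentation inflates the pivot's apparent
  distances (extra fissions), part of which melts away at coarse
  resolution when small scaffolds lose all their blocks.
* **Seeding:** one global seed fans out to fixed per-stage seeds, so any
  sub-experiment is independently reproducible.

What the generator does **not** emulate: gene-level sequences or trees,
whole-genome duplication/triplication paralogy (the three-genome design
assumes lineages that escaped post-triplication polyploidy), real
similarity/Ks thresholds, and chromosome-scale assembly errors. Passing
tests therefore demonstrate correctness of the machinery and the
qualitative resolution phenomenology, not quantitative agreement with any
particular real clade.

## Problem sizes used by the tests

The suite validates: DCJ distance against breadth-first search over single
operations, exhaustively for all genome pairs on up to five blocks (up to
relabelling); the median against exhaustive minimization on four blocks
(100+ random triples); the breakpoint-median matching weight against brute
force on five blocks; estimator recovery over 500 simulated histories; and
the end-to-end blurring effect over 20 full-size simulated datasets at
levels 0 and 70 (the representative median's distances are used — the
enumerated sets have low variance). These sizes keep the default test run
in minutes while leaving every oracle exhaustive at its scale.

## Known limitations

* Exactness of the median is certified only within the node budget and the
  component-decomposed space (see above); results outside it are flagged,
  never silent.
* Distinct-median counts depend on the canonical form and on the
  shared-adjacency reduction; they are comparable within this package
  only.
* The scenario decomposition brackets operation counts for the greedy
  family of optimal scenarios, not over all optimal scenarios.
* Block-internal gene orders are out of scope: blocks are atomic, so
  distances internal to blocks are not computed.
* The 250-gene cutoff and 21-colour scheme are domain conventions exposed
  as parameters, not re-derived.
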