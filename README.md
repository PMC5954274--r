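# granulome

Resolution effects in synteny-block ancestral genome reconstruction.

## The problem

Reconstructing an ancestral gene order from three descendant genomes — for
example a fast-evolving, scaffold-level assembly, a conservative sister
genome and an outgroup — depends on the *resolution* (granularity) of the
synteny blocks the analysis is built on. Small blocks carry fine-scale
rearrangement signal but also alignment noise, misassigned out-paralogs and
assembly artifacts; deleting them and merging their neighbours coarsens the
analysis. `granulome` quantifies what that trade-off does to every
downstream inference: the median genome, its distances to the leaves, the
translocation/reversal spectrum of the implied scenarios, the breakpoint
reuse statistic and probabilistic translocation-count estimates.

The package is aimed at comparative genomicists who work with block-order
representations of plant (or other) nuclear genomes and want to know how
robust their ancestral-genome conclusions are to the block-size threshold.

## What it computes

Genomes are sets of linear chromosomes of signed synteny blocks.

* **DCJ distance** `d(A,B) = N − (C + I/2)` from the adjacency graph of the
  two genomes (`N` blocks, `C` cycles, `I` odd paths), and the
  multichromosomal **breakpoint distance** `b = N − a − e/2` (`a` shared
  adjacencies, `e` shared telomeres).
* **Breakpoint reuse** `r = 2d/b`, which runs from 1 (every operation makes
  two fresh breakpoints) to 2 (genomes mutually randomized).
* The exact **DCJ median** of three genomes — a genome `m` minimizing
  `d(m,A)+d(m,B)+d(m,C)` — by branch-and-bound over the median's
  adjacencies, with enumeration of all co-optimal medians, plus the
  **breakpoint median** via an exact maximum-weight matching on block
  extremities.
* Optimal **sorting scenarios** decomposed into reversals, translocations,
  fusions and fissions, under either operation priority, so the
  translocation/reversal counts can be bracketed.
* A **translocation-count estimator** from conserved syntenies: with
  `c^(i)` the number of A-chromosomes leaving at least one fragment on
  B-chromosome `i`, and chromosome length fractions `p`, `q`, solve

      1 − Σ c^(i) / (c d) = (1 − 1/d)^(1 + 2 t̂ / c)

  (closed form; general unequal-length variants are solved by bisection).
* A **resolution sweep**: at level `L` every block with fewer than `L`
  genes is ignored; surviving neighbours closer than 250 genes on all
  three genomes (counting the deleted genes between them) and of the same
  ancestral colour are merged; ambiguous merged-block polarities are
  resolved by a local search on the median score.
* A **synthetic-data generator** with full ground truth: a coloured
  ancestor, three leaves evolved under genome-specific regimes,
  fractionation erosion, unaligned inter-block gaps, SynMap-like pairwise
  block tables and scaffold fragmentation of the pivot assembly.

## Worked example

```r
library(granulome)

g1 <- block_genome(list(c(1, 2, 3, 4), c(5, 6)), name = "A")
g2 <- block_genome(list(c(1, -3, -2, 4), c(5, 6)), name = "B")
dcj_distance(g1, g2)        # 1   (one reversal)
breakpoint_distance(g1, g2) # 2   (two novel breakpoints)
reuse_rate(g1, g2)          # 1   (no reuse)

cfg <- granulome_config(sim = sim_config(seed = 1),
                        schedule = resolution_schedule(levels = c(0L, 30L, 70L)),
                        enumerate = FALSE, scenarios = FALSE, polarity = FALSE)
run <- run_granulome(cfg)
run$summary[, c("level", "d_m_pivot", "d_m_sister", "d_m_outgroup",
                "t_hat_pivot", "r_pivot_sister")]
```

which prints

```
 level d_m_pivot d_m_sister d_m_outgroup t_hat_pivot r_pivot_sister
     0        40          3           15       29.40           1.69
    30        29          5           10       21.89           1.81
    70         9          3            5        8.24           1.76
```

At full resolution (level 0) the fast, translocation-rich pivot leaf sits
far from the median (`d = 40`) while the conservative sister is close
(`d = 3`); by level 70 the gap has collapsed (`9` vs `3`) — decreasing
resolution blurs the rate difference between the genomes. The
translocation estimate `t̂` for the pivot decays in parallel, because most
of its apparent interchromosomal mixing lives in small blocks.

See the methods vignette (`vignettes/resolution-effects.Rmd`) for the
model, parameter and design discussion.

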