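# splicedep

Interdependence analysis of cassette-exon (skipped-exon) regulation across
SR and hnRNP splicing-factor knockdowns.

## The problem

SR proteins and hnRNPs shape alternative splicing combinatorially: the
inclusion level (PSI, percent spliced in) of a cassette exon can respond to
the knockdown of one splicing factor or of many. Given one skipped-exon
differential-splicing table per RBP knockdown (rMATS-style), `splicedep`
asks, for every pair of RBPs, whether their *regulons* — the sets of exons
whose inclusion changes significantly upon knockdown — overlap more than
chance allows, and then characterises what distinguishes independently
regulated exons (affected by a single RBP) from interdependently regulated
ones (affected by two or more).

The overlap statistic is the hypergeometric survival function. For a pair
of RBPs with regulon sizes *M* and *n* drawn from a shared universe of *N*
exons and observed overlap *m*:

    sf(m; N, M, n) = P(X >= m) = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M, n-i) / C(N,n)

A pair is called interdependent when `sf(m) <= 0.05`. The tail sum is
accumulated in log space so that strongly co-regulated pairs (p-values far
below double-precision products of binomial coefficients) are still exact.

Around the pair test the package provides:

- **I/O**: readers for rMATS `SE.MATS.JC`-style and canonical TSV dialects
  (unit, sign, and coordinate conventions normalised), duplicate-exon
  collapse, exon feature tables.
- **Filtering**: the two stock significance policies — `|dPSI| > 0.15`
  (HeLa-style) and `|dPSI| > 0.10 & FDR <= 0.05` (ENCODE-style).
- **Interdependence**: all-pairs testing, the row-normalised
  interdependence matrix (what share of a row RBP's interdependent exons
  each column RBP also affects), complete-linkage clustering.
- **Populations**: enhancer/silencer direction summaries, regulator
  multiplicity, direction consistency by multiplicity, wildtype-PSI
  distributions, and feature-vs-multiplicity regressions (5' / 3' splice
  site strength, PhyloP, exon and intron lengths).
- **Cross-cell-line context**: relative RBP importance, pairs significant
  in every line, per-RBP cross-line regulon Jaccard, and cross-RBP
  (indirect) regulation detection.
- **Synthetic data**: a generator with planted ground truth (regulon
  sizes, pair overlaps, direction biases, PSI mixtures, feature slopes) so
  the whole pipeline is testable without downloads.

## Worked example

The `analysis/` directory holds the full numbered workflow. A minimal
session:

```r
library(splicedep)

ds   <- generate_synthetic(synthetic_config(seed = 20260925,
                                            cell_lines = c(HeLa = 1, K562 = 0.2)))
regs <- synthetic_regulons(ds)              # dedup + |dPSI| > 15% filter

pairs <- all_pairs(regs, alpha = 0.05)
mat   <- build_matrix(regs, pairs)
prof  <- build_multiplicity(regs)
```

Running the workflow scripts on these conditions prints, among others:

```
435 pair tests; 41 significant at alpha 0.05 (9.4%)
per-RBP interdependent-exon fraction: median 60%, range 26-79%
multiplicity: 67.6% of 1540 exons touched by a single RBP; max 5 RBPs per exon
mixed-direction regulation rises from 0% (bin 1) to 100% (bin 5)
intermediate wildtype inclusion (PSI 0.35-0.65): 3.7% of independent vs 48.9% of interdependent exons
ss5_score vs multiplicity: slope -0.371 (r^2 0.97, p 0.00256)
```

Reading: of the 435 possible RBP pairs, 41 overlap more than chance;
most affected exons respond to a single knockdown; exons touched by many
RBPs are increasingly regulated in both directions, sit at intermediate
wildtype inclusion, and carry weaker 5' splice sites — the planted
trend of −0.4 bits per additional regulator is recovered within its
confidence interval.

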