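---
title: "Methods: quantifying interdependent regulation of exon skipping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying interdependent regulation of exon skipping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicedep)
```

## The model

`splicedep` treats each RBP knockdown as defining a *regulon*: the set of
cassette exons whose inclusion level changes significantly when that
factor is depleted. Two RBPs are *interdependent* regulators when their
regulons overlap more than expected for two fixed-size sets drawn at
random from a common exon universe. Under that null, the overlap $m$ of
sets of sizes $M$ and $n$ in a universe of $N$ exons is hypergeometric,
and the test statistic is the upper tail (survival function)

$$\mathrm{sf}(m; N, M, n) \;=\; P(X \ge m) \;=\;
  1 - \sum_{i=0}^{m-1} \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}}.$$

A pair with $\mathrm{sf}(m) \le \alpha$ (default $\alpha = 0.05$, raw
p-values over all $k(k-1)/2$ pairs) is called significantly
interdependent. The assumptions this encodes:

- exons are exchangeable within the universe (no per-exon propensity to
  be affected by *any* knockdown);
- the two regulons are conditionally independent given their sizes under
  the null;
- direction of regulation is ignored at this stage — an overlap counts
  whether the two knockdowns move inclusion the same way or not.

The universe $N$ is the size of the **union** of the two deduplicated,
unfiltered tables. "Combined" could also be read as the *sum* of the two
table sizes, but a hypergeometric draw is from a set, and double-counting
shared exons would inflate $N$ and anti-conservatively deflate p-values;
the sum variant is kept available (`universe = "sum"`) for sensitivity
analysis.

Exon identity throughout is `(chrom, strand, exon_start, exon_end)`,
deliberately excluding the flanking-exon coordinates: the same cassette
exon reported with two different flanking pairs must count once in any
overlap. Duplicate rows are collapsed to the record with the largest
|dPSI| (ties: smallest FDR, then first occurrence) — the strongest
evidence that the exon responds at all.

## Filter policies

Two stock policies mirror the two kinds of source data:

| policy | rule | rationale |
|---|---|---|
| `hela_policy()` | \|dPSI\| > 0.15 | tables without usable statistics; threshold on effect size only |
| `encode_policy()` | \|dPSI\| > 0.10 and FDR ≤ 0.05 | tables with per-event FDR |

The dPSI inequality is strict ("greater than 15%"), the FDR bound
inclusive ("FDR ≤ 0.05"). Thresholds are applied to |dPSI| — exons are
binned by sign *after* filtering, so the filter itself is two-sided. PSI
and dPSI are handled internally as fractions; readers rescale
percent-unit sources (auto-detected when any |value| exceeds 1). Records
with missing dPSI are excluded from both the regulon and the universe
(they can support neither the numerator nor the null draw) and surfaced
in `n_dropped_missing_dpsi`.

An exon whose inclusion *decreases* upon knockdown is scored as enhanced
by the RBP in wildtype; an increase marks silencing. One exon may be an
"increase" for one RBP and a "decrease" for another; direction summaries
are per-RBP by design.

## Populations and derived statistics

*Multiplicity* is the number of regulons containing an exon, computed
over the union of affected sets from one cell line and one policy. Exons
with multiplicity 1 form the *independent* population, multiplicity ≥ 2
the *interdependent* one. Derived summaries:

- the interdependence matrix: cell $(r, c)$ is the percentage of row
  RBP $r$'s interdependent exons also affected by column $c$, so every
  cell lies in $[0, 100]$. On the diagonal this means intersecting with
  the row's own interdependent set (100 whenever the row has any
  interdependent exon); off-diagonal it coincides with intersecting full
  regulons. Matrices are kept at full precision and rounded only for
  display.
- direction consistency per multiplicity bin (`increase_only`,
  `decrease_only`, `both`); bin 1 cannot be `both` by construction.
- wildtype-PSI distributions of the independent vs interdependent
  populations, with the fraction at *intermediate inclusion* — fixed as
  PSI ∈ [0.35, 0.65], a symmetric window around 50% inclusion
  (configurable; any "~50%" convention is necessarily arbitrary).
- per-feature regressions of bin mean against multiplicity for the six
  exon features (5'/3' splice-site strength in MaxEnt bits, PhyloP
  conservation, exon length and both intron lengths in nt). Bins with
  zero exons are dropped, never interpolated; at least three occupied
  bins are required.

### Weighting the feature regression

The default fit is ordinary least squares over the bin means with one
observation per bin, which treats every multiplicity bin as equally
informative. Because a bin mean of $n_k$ exons has sampling variance
$\sigma^2/n_k$, these observations are heteroscedastic, and the
unweighted CI undercovers slightly when the top bins hold a handful of
exons. `feature_trend(weighted = TRUE)` weights bins by exon count,
which matches that variance structure exactly and yields calibrated 95%
intervals; the parameter-recovery checks in the test suite therefore use
the weighted fit, while the unweighted fit remains the default reporting
path. The regression's null calibration is verified on balanced bins
(equal $n_k$), where the OLS assumptions hold exactly and p-values are
uniform by construction.

Clustering of the interdependence matrix uses Euclidean distance with
complete linkage via `stats::hclust`, the same procedure the heatmap
packages in this field delegate to; rows are pre-sorted lexicographically
so the dendrogram is deterministic for a given matrix.

## Numerical choices

- `hypergeom_sf` accumulates $\sum_i \exp(\log\binom{M}{i} +
  \log\binom{N-M}{n-i} - \log\binom{N}{n})$ via log-sum-exp. Naive
  arithmetic fails in exactly the regime of interest: a strongly
  co-regulated pair can have $m = 200$, $M = n = 400$, $N = 20000$,
  where $\binom{400}{200} \approx 10^{119}$ overflows long before the
  p-value ($\sim 10^{-248}$) does. Results are clamped to $[0, 1]$;
  $m \le 0$ returns exactly 1 and $m > \min(M, n)$ exactly 0.
- Tails below ~$10^{-308}$ are not representable in doubles; the package
  returns 0 there, which cannot affect any significance call.
- A pair with $m = 0$ is reported with status `no_overlap` (p = 1),
  distinguished from `tested`-but-not-significant so three-state
  summaries remain drawable.
- Degenerate inputs: an empty population reports `NA` percentages rather
  than 0/0; constant features report slope 0, $r^2$ 0, and no test;
  a full-overlap pair ($m = M = n = N$) has p = 1 (the event is certain).

## The synthetic generator

`generate_synthetic()` emulates the statistical shape of SR/hnRNP
knockdown studies so every stage has planted ground truth. Defaults are
the package's standard study conditions:

| parameter | default | emulates |
|---|---|---|
| `n_rbps` | 30 | 9 SR + 21 hnRNP knockdowns |
| `universe_size` | 5000 | detected skipped-exon events per table |
| `regulon_sizes` | log-uniform 3–300 | the observed spread from a handful to ~300 affected exons |
| planted overlaps | pair prob 0.15, 25% of smaller regulon | co-regulated exon blocks |
| `enhancer_bias` | 0.65 | the observed tilt toward enhancement of inclusion |
| affected \|dPSI\| | 0.15 + 0.85·Beta(2, 5) | right-skewed knockdown effect sizes |
| wildtype PSI | ½Beta(1,9) + ½Beta(9,1), + Beta(5,5) weight → 0.4 at multiplicity ≥ 4 | bimodal inclusion, with interdependent exons drifting to intermediate PSI |
| `feature_model` | ss5 slope −0.4 bits, PhyloP −0.08 per regulator; weak length trends | weaker splice sites and conservation shifts at high multiplicity |

Determinism: a fixed RNG algorithm (Mersenne–Twister, inversion,
rejection sampling) is set for the duration of generation and the
caller's RNG state restored, so one config yields one dataset on any
platform. Every planted affected row passes both stock filter policies
(|dPSI| > 0.15, FDR ≤ 0.05) and every background row fails both, so
filters recover the planted truth *exactly* — filter tests are sharp,
not statistical. Feasibility guards: auto-planting caps a regulon's
summed planted overlap at 60% of its size; magnitudes are capped at 0.98
(0.49 when an exon is pushed in both directions) so a wildtype PSI
compatible with every planted change always exists; wildtype PSI is then
drawn from the mixture truncated to the feasible interval.

What the generator does **not** emulate — and hence what green tests do
not show about real data: no shared exon-level propensity (real "hot"
exons violate the exchangeability null), no correlation between regulon
membership and feature values beyond the planted linear trends, no
replicate structure or read-level noise behind the PSI values, no genome
sequence (coordinates are synthetic non-overlapping intervals), and no
indirect-effect structure (cross-RBP regulation is tested on explicit
fixtures instead). Dataset-scale results on real knockdown tables — the
fraction of significant pairs, per-RBP affected counts, maximum
multiplicity — are properties of those datasets, not of this package,
and are not asserted anywhere.

`null_resample()` strips all planted structure while preserving marginal
regulon sizes; it backs the calibration claim that the discrete test's
rejection rate at $\alpha = 0.05$ stays at or below nominal
(conservative, as exact discrete tests are).

## Problem sizes used in the checks

The suite verifies the survival function against exact
binomial-coefficient arithmetic over the full grid $N \le 25$ (and
against brute-force subset enumeration for $N \le 10$); calibration on
2175 independent null pairs (30 RBPs × 5 replicates, universe 5000);
power on 200 planted replicates (regulon sizes 30/30, overlap 10 —
Jaccard 0.2 — universe 5000); and slope recovery on 100 replicates of a
12-RBP, universe-1000 study with size-150 regulons, a design whose
multiplicity bins stay well populated. These sizes were chosen to make
each check statistically meaningful at desk scale.

## Known limitations

- The hypergeometric null ignores per-exon detectability differences;
  against real data the test is anti-conservative for exons that are
  easy to call in every knockdown.
- No multiple-testing correction by default, matching the raw
  p ≤ 0.05 convention over 435 pairs; `adjust = "BH"` is available and
  strictly shrinks the significant set.
- Direction-aware overlap testing (same-sign vs opposite-sign
  co-regulation) is out of scope; the pair test pools both directions.
- Cross-cell-line exon comparisons assume one genome build; no liftover
  is attempted.
- Feature values are consumed as a precomputed table; the package never
  computes splice-site or conservation scores from sequence.
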