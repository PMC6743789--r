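---
title: "Methods: temporal analysis of chromatin accessibility and expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal analysis of chromatin accessibility and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromdyn)
```

## The problem

During *Drosophila* wing metamorphosis, cells move from a proliferative
state through a final synchronised cell cycle into a postmitotic G0, while
the open-chromatin landscape (measured by FAIRE-seq) and the transcriptome
(RNA-seq) are resampled at six stages: wandering third instar (L3) and 6,
18, 24, 36 and 44 hours after puparium formation. chromdyn implements the
downstream analysis of such a paired time course: which open-chromatin
peaks change, how they change over time, which genes they plausibly
regulate, how accessibility changes relate to expression changes, and
whether particular transcription-factor motifs are over-represented in a
peak class. A seeded synthetic generator reproduces the assumed data
structure with ground truth so every stage of the analysis is testable
without any sequencing data.

## Models and procedures

### High-fidelity peak selection

Accessibility (RPKM) is standardised per chromosome arm: for stage $s$ and
arm $a$, $Z_{is} = (x_{is} - \mu_{as}) / \sigma_{as}$, with $\mu$ and
$\sigma$ the mean and population standard deviation over the arm's peaks.
A peak is high-fidelity when $\max_s Z_{is} > 2$ (strict inequality).
Using the population rather than the sample standard deviation is a
convention choice; at arm scale (hundreds to thousands of peaks) the two
are indistinguishable. Arms with a single peak or zero spread at a stage
get $Z = 0$ there, with a warning, rather than an error — degenerate arms
occur routinely in subset analyses.

Applied to a log-normal signal universe, this filter retains roughly the
upper tail of each arm (about a fifth of the synthetic default dataset).
Published high-confidence peak tables have typically already been through
such a selection, which is why `run_pipeline()` exposes
`apply_z_filter`: leave it `TRUE` for raw peak tables, set it `FALSE`
when the input is already a high-confidence set — the synthetic generator
emulates the latter.

### Static and dynamic peaks

With pseudocount $c$ (default 0.1 RPKM), the maximal pairwise fold change
of a row is $(\max_s x + c) / (\min_s x + c)$. A peak is **static** when
this ratio is strictly below the threshold (default 2), **dynamic**
otherwise; this is exactly the all-pairs reading of "changes less than
2-fold between any two time points". The pseudocount guards against
division by zero at silent peaks and is deliberately configurable:
`replicate_supplementary()` sweeps it over $\{0, 0.1, 1\}$ because the
published counts were computed from an unspecified zero-handling
convention. Per-transition labels use the same ratio between adjacent
stages: opening above the threshold, closing below its reciprocal, flat
otherwise.

Dynamic **genes** add an expression floor: RPKM strictly above 1 in at
least one stage, and a maximal pairwise fold change of at least 2.

### Temporal clustering and cluster categories

Peaks are normalised to their fraction of maximum (each row divided by its
row maximum; all-zero rows stay zero and are flagged) so clustering
compares temporal shape, not amplitude. Clustering is Euclidean k-means
with k-means++ initialisation, the best of 10 seeded restarts by total
within-cluster sum of squares, which makes results reproducible from the
configured seed — plain `stats::kmeans()` with random starts is not. The
default `k = 18` follows common practice of over-clustering a six-point
profile space and then grouping clusters by category; for the synthetic
data, analyses use `k` equal to the number of planted classes (10).

Centroids are categorised with two explicit thresholds: stages at or above
`on_threshold = 0.7` of maximum are "on"; a centroid whose spread
(max − min) is below `flat_range = 0.3` is *flat*; exactly one on-stage is
*sharp*; two or more contiguous on-stages are *broad*; non-contiguous
on-stages are *oscillating*. The categories are described only
qualitatively in the literature; these thresholds make them operational
and are exposed in `analysis_config()`. A centroid that is not flat by
spread but has no stage reaching the on-threshold is labelled flat as
well — this cannot happen for raw fraction-of-max rows (whose maximum is
1) but can for centroids, and flat is the only category that does not
presuppose an on-stage.

### Peak-to-gene assignment

Each peak is assigned to the gene whose TSS minimises the absolute
distance to the peak midpoint (`floor((start + end) / 2)`) on the same
chromosome; equidistant ties go to the lexicographically smallest gene id
for determinism. The signed distance is strand-aware: positive when the
midpoint lies downstream of the TSS in the gene's orientation. For genes
with several transcripts the 5′-most TSS on the gene strand is used —
the published analysis does not state its choice, so multi-TSS genes are
the one place replication of per-peak assignments may differ. Feature
categories are decided at the midpoint with priority
promoter > 5′UTR > CDS > intron > 3′UTR > non-coding gene > intergenic,
the proximal promoter being the strand-aware −500..+150 bp window around
the assigned TSS. Distance histograms use half-open kb bins
[0, 0.5), [0.5, 1), [1, 5), [5, 10), [10, ∞).

All coordinates are 0-based half-open internally; GTF-like input (1-based
closed) is converted on read, so a gene starting at GTF position 1001 on
the + strand has TSS 1000. One convention everywhere avoids off-by-one
drift between modules.

### Accessibility × expression integration

For each stage against its next two sequential stages, the peak's
accessibility log2 fold change and its assigned gene's expression log2
fold change (both with pseudocount) are classified jointly: a pair enters
a quadrant (`open_up`, `open_down`, `close_up`, `close_down`) only when
both magnitudes reach $\log_2$(fold threshold); otherwise it is `ns`. The
published analysis additionally required replicate-level adjusted
p-values; that needs a count-level differential test outside this
package's scope, so `pairwise_quadrants()` accepts an optional
user-supplied per-peak significance mask instead — with no mask the
2-fold rule alone decides.

Trajectory coupling is quantified per gene–peak pair as the Pearson
correlation between the gene's log2 fold-change trajectory (vs the first
stage) and the peak's fraction-of-max trajectory, aggregated per
expression cluster (median and quartiles) together with the correlation
of the two cluster-mean trajectories. Pairs where either trajectory is
constant are excluded and counted — a correlation is undefined there.

Gene-set accessibility profiles compare each stage's per-peak signal with
the reference stage by a two-sided Mann-Whitney U test: exact (null
permutation distribution, $p = 2\min(\text{tails})$ capped at 1) when
$n_1 + n_2 \le 20$ with no ties, otherwise the normal approximation with
tie and continuity corrections; an all-tied comparison returns $p = 1$.
Gene-set over-representation uses the upper-tail hypergeometric
probability. MA tables use $A = \tfrac12\log_2((a+c)(b+c))$,
$M = \log_2((a+c)/(b+c))$.

### Motif analysis

Known-motif scanning replaces de novo discovery. Count matrices become
probability matrices with a per-base pseudocount (default 0.25);
scanning slides the log2-odds score
$\sum_i \log_2(p_{i,b}/q_b)$ over both strands (windows containing N are
skipped) and keeps windows whose score reaches a fraction (default 0.8)
of the maximal attainable score. A fraction-of-maximum threshold is
deterministic and directly interpretable ("high-scoring sites"); a
score-distribution p-value mode would be the natural extension. The
background is uniform by default. Degenerate motifs whose maximal score
is not positive yield no hits by definition.

Enrichment counts peaks with at least one hit (robust to peak-length
variation, unlike hit counts), forms the 2×2 table against a background
peak set, and applies Fisher's exact test (two-sided as the sum of table
probabilities not exceeding the observed one). The reported odds ratio is
the sample odds ratio with a Haldane correction of 0.5 per cell when any
cell is zero.

## The synthetic generator

`simulate_dataset()` emulates the structure the analysis assumes, not
sequencing reads:

* **Stages and geometry.** Six stages; 2,000 peaks of width 200 bp placed
  without overlap on five arms (2L, 2R, 3L, 3R, X) of 2 Mb each by
  jittered regular spacing. (The published dataset has ~20k peaks; a
  tenth of that preserves every class at ample size while keeping the
  full test suite and workflow in seconds.)
* **Classes.** 25% static; the dynamic remainder split equally over six
  sharp classes (amplitude 4 at one stage), two broad classes (stages
  18–36h and 24–44h) and one oscillating class (L3/18h/36h). Amplitude 4
  sits safely above the 2-fold threshold so recovery failures indicate
  bugs, not borderline arithmetic.
* **Signal.** `baseline × profile × exp(N(0, σ²))` with log-normal
  baselines (meanlog 2, sdlog 0.5 — median ≈ 7 RPKM) and multiplicative
  noise σ = 0.15, a typical residual spread for deeply sequenced
  bulk assays. Replicates add σ = 0.1 around the stage signal.
* **Genes.** Each of 1,000 genes couples to a distinct peak: 60%
  activation (expression proportional to the peak profile), 20%
  repression (inverted), 20% decoupled (independent profile). The TSS
  sits 150 bp from the partner peak's midpoint, so nearest-TSS assignment
  recovers the planted partner (≥ 99%); simple two-exon gene models
  (5′UTR, split CDS, intron, 3′UTR, 2 kb span) support the feature and
  length statistics, with 2% non-coding genes.
* **Motif.** The consensus `TGACGTCA` is overwritten into 30% of dynamic
  and 5% of static peak sequences at uniform offsets, with records.

What the generator does **not** emulate: count-level (negative-binomial)
noise and replicate-based significance, mappability and GC structure,
overlapping or nested genes, multi-TSS isoform choice, distance-dependent
enhancer–gene wiring, and realistic motif background composition. Passing
recovery tests therefore demonstrates the correctness of the
implementation under the stated model, not performance on real data.

## Numerical choices and degenerate inputs

* Pseudocount 0.1 RPKM before every ratio; configurable, swept in
  replication analyses.
* Strict inequalities follow the verbal rules: static is `< fold`,
  high-fidelity is `Z > 2`, the expression floor is `RPKM > 1`; dynamic
  is `>= fold`.
* k-means: k-means++ seeding, 10 restarts, Lloyd fallback where
  Hartigan–Wong rejects a degenerate configuration (e.g. k equal to the
  number of rows); assignments are deterministic given the seed.
* All-zero rows in fraction-of-max stay zero and are flagged; zero-spread
  arms give Z = 0 with a warning; zero-variance trajectories are excluded
  from correlations and counted.
* Exact Mann-Whitney requires tie-free input; with ties the tie-corrected
  normal approximation is used at any size.

## Problem sizes

The test suite exercises oracle equivalence at 50–200 random rows,
100 × 50 nearest-TSS instances, all Mann-Whitney layouts with
$n_1+n_2 \le 8$, Fisher tables with margins ≤ 30, and parameter recovery
on the 2,000-peak synthetic default; the whole suite and the acceptance
script each run in well under a minute on one CPU.

## Known limitations

* Replicate-aware differential testing (negative-binomial models) is out
  of scope; the significance mask hook is the integration point.
* The promoter-priority order and the cluster-category thresholds are
  operational conventions for qualitative published descriptions; results
  near those boundaries depend on them.
* Multi-TSS genes use the 5′-most TSS; per-peak assignments may differ
  from analyses that used another transcript choice.
* The motif module scans known PWMs only; it does not discover motifs.
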