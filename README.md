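# chromdyn

Temporal analysis of chromatin accessibility and gene expression across a
developmental time course.

`chromdyn` is for genomicists working with open-chromatin time courses
(FAIRE-seq or ATAC-style RPKM tables) paired with RNA-seq over the same
stages — the setting of *Drosophila* wing metamorphosis sampled at L3 and
6, 18, 24, 36 and 44 h after puparium formation, where coordinated waves of
chromatin opening and closing accompany the exit from the cell cycle into a
terminally differentiated state. The package implements the standard
downstream battery for such data as tested, seed-reproducible functions,
plus a synthetic generator with ground truth so the whole pipeline can be
exercised and validated without sequencing data.

## What it computes

* **High-fidelity peaks** — per chromosome arm and stage,
  `Z[i,s] = (x[i,s] − μ(arm,s)) / σ(arm,s)` (population σ); keep peaks with
  `max_s Z > 2`.
* **Static/dynamic classification** — with pseudocount `c`, a peak is
  static iff `(max_s x + c)/(min_s x + c) < 2` (all pairs of time points);
  per-transition opening/closing labels use the same ratio between
  adjacent stages. Dynamic genes additionally require RPKM > 1 at some
  stage.
* **Temporal clustering** — fraction-of-maximum profiles
  (`x / max_s x`), Euclidean k-means with k-means++ seeding and
  best-of-10 restarts, and centroid categories: *sharp* (one "on" stage),
  *broad* (contiguous on-stages), *oscillating* (non-contiguous), *flat*.
* **Peak-to-gene assignment** — nearest TSS by midpoint distance with
  strand-aware signed distances, feature categories
  (promoter > 5′UTR > CDS > intron > 3′UTR > nc gene > intergenic,
  promoter = −500..+150 bp), distance-bin histograms, interval overlaps,
  gene-structure length statistics.
* **Accessibility × expression integration** — quadrant classification
  (open_up / open_down / close_up / close_down at joint 2-fold changes,
  each stage vs its next two), gene/peak trajectory correlations per
  expression cluster, gene-set accessibility profiles with two-sided
  Mann-Whitney U tests (exact when `n1+n2 ≤ 20`, tie-free), hypergeometric
  gene-set enrichment, MA tables.
* **Motif analysis** — PWMs from count matrices (pseudocount 0.25),
  log2-odds scanning of both strands at ≥ 80% of the maximal score, and
  Fisher exact enrichment of peaks-with-a-hit in a foreground vs a
  background peak set.
* **Synthetic time courses** — `simulate_dataset()` plants static,
  sharp, broad and oscillating peak classes (amplitude 4, log-normal
  baselines, multiplicative noise), activation/repression/decoupled
  peak–gene couplings, replicates, gene models and motif-bearing
  sequences, all with ground truth and byte-identical reruns per seed.

## Worked example

The `analysis/` scripts run the whole workflow over a synthetic dataset
(`01_simulate.R` → `06_motifs.R`, writing tables under `results/`). In
miniature:

```r
library(chromdyn)

cfg <- simulation_config(n_peaks = 2000, rng_seed = 7)   # 25% static planted
ds  <- simulate_dataset(cfg)
rep <- run_pipeline(ds, analysis_config(k_clusters = 10, rng_seed = 7),
                    motif = consensus_pwm(cfg$motif_consensus),
                    apply_z_filter = FALSE)   # input is already high-confidence
rep
#> Time-course analysis report
#>   peaks: 2000 input, 2000 high-fidelity
#>   static 493 (24.6%), dynamic 1507 (75.4%)
#>   dynamic genes: 762
#>   cluster categories: broad=2, flat=1, oscillating=1, sharp=6
rep$motif_enrichment$p
#> [1] 2.709112e-40
```

Reading the output: the pairwise 2-fold rule recovers the planted 25%
static fraction (493/2000 called static); the ten k-means centroids over
fraction-of-max profiles sort into the planted sharp/broad/oscillating
categories plus one flat centroid capturing the static peaks; and the
planted motif (30% of dynamic vs 5% of static peak sequences) is detected
as strongly enriched in dynamic peaks by Fisher's exact test. With
`apply_z_filter = TRUE` the same call instead restricts the downstream
stages to peaks whose per-arm accessibility Z-score exceeds 2 at some
stage — the selection rule for high-fidelity peaks in raw tables.

`replicate_supplementary()` (and `analysis/07_replicate_supplementary.R`)
applies the same static/dynamic and dynamic-gene rules to published
per-peak and per-gene RPKM tables exported as TSV, sweeping the ratio
pseudocount over {0, 0.1, 1}.

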