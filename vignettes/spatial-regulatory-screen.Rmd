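---
title: "Methods: spatial coexpression and cis-element screening of TF regulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial coexpression and cis-element screening of TF regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotnet)
```

## The problem

Transcription factors (TFs) can only regulate a structural gene if two
things are true at once: the TF must be expressed where the target is
expressed, and the target's promoter must contain a binding site the TF
can recognize. Spatial transcriptomics makes the first condition directly
observable. `spotnet` implements a screen built on that idea — call it
spatial determinism of regulation — for nominating TF regulators of
metabolite pathways (the motivating system is tea shoot tissue, where the
pathway sets are catechin synthesis, theanine hydrolysis and caffeine
synthesis, and the screen's job is to surface TFs such as a TCP-family
dual regulator of the first two): spots are clustered into tissue
domains, genes are grouped into spatial coexpression modules, promoters
are scanned for family binding motifs, and TF–target edges are kept only
when *both* lines of evidence agree.

## Pipeline model

The analysis operates on a spots × genes matrix of deduplicated UMI
counts plus a gene annotation (TF flag, TF family, pathway tags), a
promoter sequence per gene, and one position weight matrix (PWM) per TF
family.

1. **QC and normalization.** Spots with fewer than `min_counts_per_spot`
   (default 100) total UMIs and genes detected in fewer than
   `min_spots_per_gene` (default 3) spots are dropped. Counts are
   library-normalized to `log(1 + count * 1e4 / total)` (log1p-CPM with a
   10,000 scale factor, the dominant convention for UMI data).
2. **Embedding and clustering.** PCA (default 30 components, genes
   centred and unit-scaled, top 2000 highly variable genes by
   variance/mean dispersion) feeds a k-nearest-neighbour graph
   (k = 15, Euclidean) with shared-nearest-neighbour Jaccard edge
   weights, clustered by Louvain modularity optimization
   (`igraph::cluster_louvain`). Labels are re-indexed by decreasing
   cluster size. The resolution (default 1.0) is a free parameter: the
   package does not promise any particular cluster count on arbitrary
   data, and `sweep_resolution()` bisects toward a requested count when
   one is wanted.
3. **Markers.** One-vs-rest two-sided Wilcoxon rank-sum per gene, with
   Seurat-style prefilters (detected fraction ≥ 0.1 in-cluster, log2
   fold change ≥ 0.25) and Benjamini–Hochberg correction across the
   tested set.
4. **Coexpression modules.** Spots are collapsed to per-cluster
   pseudo-bulk means, genes whose maximum profile value falls below 0.1
   are dropped, rows are z-scored (sample sd, ddof 1), and K-means with
   K = 9 groups the standardized profiles.
5. **Binding sites.** Each structural gene's promoter is scanned on both
   strands with every family PWM; windows are scored by log2 odds
   against a uniform background and placed on a relative 0–1 scale
   between the PWM's analytic minimum and maximum; hits require relative
   score ≥ 0.85.
6. **Network and ranking.** Edge TF → target iff (a) ≥ 1 hit of the
   TF's family in the target promoter and (b) spatial consistency:
   shared K-means module **or** Pearson r ≥ 0.8 between standardized
   cluster profiles. TFs are then ranked lexicographically by (pathway
   sets covered, distinct targets covered, mean spatial r), ties broken
   by gene id.

## Parameters that matter

| parameter | default | unit/meaning | rationale |
|---|---|---|---|
| `scale_factor` | 1e4 | pseudo-counts per spot | standard log1p-CPM convention |
| `n_pcs` | 30 | PCA components | generous for 3–9 domain structures |
| `knn_k` | 15 | neighbours per spot | common SNN default |
| `resolution` | 1.0 | Louvain resolution | free parameter; see above |
| `min_expr` | 0.1 | min max pseudo-bulk log-expression | "filter low expression" made concrete as a package default |
| `K` | 9 | coexpression modules | the reference configuration |
| `rel_threshold` | 0.85 | relative PWM score in [0,1] | simplest reproducible convention for binding-site calls |
| `rho_min` | 0.8 | min profile correlation | "consistent expression trend" made concrete |
| `require_module` | FALSE | module co-membership mandatory? | the dual criterion accepts either spatial reading |

Two deliberate interpretation points:

* **Clamping standardized profiles.** Heatmap-oriented K-means
  workflows often truncate extreme z-scores (bounds like 0.6 or 1 are
  common) so that a single outlying cluster does not dominate the
  distance. `standardize_profile()` exposes this as an optional
  symmetric `clamp`, **default off**: truncation changes the geometry
  the modules are fit in and should be a deliberate choice, not a
  silent one.
* **Module co-membership OR correlation.** Whether spatial consistency
  was enforced as module co-membership, a correlation floor, or either
  is unstated; both are implemented, the OR is the default, and
  `require_module = TRUE` gives the stricter conjunction.

## The synthetic testbed

Real spatial data for this system live in a public accession and are not
shipped; every downstream stage is instead validated on a generator
whose defaults *are* the study conditions used by the tests:

* a 50 × 30 spot lattice (1500 spots) split into 3 vertical band
  domains (`voronoi` layout available for irregular shapes);
* 900 genes in 9 modules; module × domain activity follows
  `exp(a * cos(2πm/9 − 2πd/3))` with `a` set so each module's
  max/min activity ratio is ≥ 4 — the nine modules sit at equal angles
  on the circle of standardized profiles, so adjacent modules correlate
  at cos(40°) ≈ 0.77, just below the 0.8 edge threshold;
* counts are negative binomial with mean
  `lib_s · base_mean_g · activity[m, d]`, a shared dispersion (size 2),
  log-normal gene baselines (sdlog 1) and per-spot library factors
  (sdlog 0.3) — calibration choices in the realistic range for UMI
  data, fixed once;
* nine TF genes, one per module and family; a TCP-family TF in module 4
  regulates two catechin-synthesis and two theanine-hydrolysis genes in
  its own module, a bHLH and a MYB TF each regulate two genes of a
  single set, and each pathway set carries two *unregulated* genes
  coexpressed with the TCP TF — so promoter evidence is genuinely needed
  to separate regulation from coexpression;
* promoters are uniform random sequences with one exact-consensus
  family-motif instance planted per true edge (random offset and
  strand); chance hits in background promoters are allowed on purpose —
  they are exactly what the spatial criterion must reject;
* the knockdown generator draws control replicates of the TF at a
  baseline mean and knockdown replicates at `delta` times it, shifts
  each target by `sign · beta · (TF deviation)`, and composes
  metabolites as signed weighted sums of pathway-gene expression — the
  catechin readout loads positively, the theanine readout negatively.

TF expression is generated from the module activity plus independent
noise, *not* from the targets, so the analysis must rediscover the
regulatory link rather than read it off.

What the generator does **not** emulate: tissue morphology, per-spot
cell-type mixtures (deconvolution is out of scope), spatially smooth
within-domain gradients, gene-specific dispersions, and sequencing-level
artifacts. Passing tests therefore demonstrate that the pipeline
recovers planted structure under the stated noise model, not that it
is robust to everything real Visium data can do.

## Numerical choices

* **PCA signs** are fixed by making the largest-magnitude loading of
  each component positive, so embeddings are deterministic.
* **K-means** uses k-means++ initialization, 10 restarts, Lloyd
  iterations with nearest-centroid ties broken toward the lowest module
  index, and reseeds an emptied cluster from the farthest point. Seeding
  is position-keyed (the RNG draws row indices), so a permutation of the
  gene rows can change which local optimum a given seed reaches;
  stability is instead guaranteed and tested at fixed seed, and on
  separated data the recovered partition is seed-independent.
* **Rank-sum tests** use mid-ranks for ties; when both groups have ≤ 8
  observations the permutation null is enumerated exhaustively,
  otherwise the tie-corrected normal approximation is used.
* **Constant profiles** have no defined correlation; such pairs are
  flagged missing and disqualified from edges rather than defaulted
  to r = 0. Constant genes standardize to all-zero rows (with a
  warning) instead of being dropped, keeping indices aligned.
* **'N' bases** void a scan window entirely rather than scoring as
  background — conservative, and exact-consensus recall is unaffected.
* **Motif evidence is family-level**: any hit of a TF's family counts
  for that TF. This mirrors a family-resolution network display and is
  the honest granularity when the motif library is keyed by family; it
  also means co-family TFs inherit each other's binding evidence and
  must be separated by the spatial criterion alone.
* All randomness flows from one root seed; each stage derives its own
  sub-seed, so artifacts are byte-identical across same-seed runs.

## Problem sizes used by the test-suite experiments

Recovery properties are checked over 50 seeds at the default conditions
(1500 spots, 900 genes); the replicate-consistency analog uses a
homogeneous 1000-spot, 2000-gene section; statistical calibration uses
2000 null replicates (correlation, n = 20) and 200 null enrichment runs
(universe 5000, 10 terms of 500, draws of 1000). These sizes were chosen
as the smallest at which the binomial noise of a 45-of-50 style check is
well separated from the expected pass rates.

## Known limitations

* Louvain at a fixed resolution may split or merge true domains on data
  with weak contrast; ARI-based checks use the default resolution and
  the stated contrast (≥ 4×).
* The PWM scanner's relative-score threshold is not calibrated to any
  external binding-site predictor; absolute hit counts will differ from
  tools with p-value-based cutoffs.
* Edges are undirected evidence summaries with a TF → target
  convention; activation vs repression is not called (that requires
  perturbation data, emulated here only by the knockdown generator).
* Enrichment is flat hypergeometric over term sets; no ontology
  topology.
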