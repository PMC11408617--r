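---
title: "Methods: spatial niche detection, distance statistics, and signature scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial niche detection, distance statistics, and signature scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spatialniche)
```

# The model

`spatialniche` treats a segmented multiplexed image as a marked point
pattern: cells at pixel coordinates (image convention — origin top-left, y
increasing downward) carrying a cell-type mark from a fixed vocabulary. The
pipeline's object of inference is the *spatial community*: a group of cells
whose local neighborhoods share a cell-type composition, interpreted as a
tissue niche (a tumor nest, an inflammatory band, stroma).

The procedure is deliberately simple and fully deterministic given seeds:

1. **Neighborhoods.** Each cell's neighborhood is its k nearest other cells
   of the same sample under Euclidean pixel distance (default k = 100; the
   ranking is scale-invariant, so no unit conversion is needed here). Ties
   in distance are broken by ascending row index. The neighborhood is
   summarized as a proportion vector over the type vocabulary. By default
   the index cell itself is counted too (a window of k + 1 cells): the
   precedent neighborhood-analysis scheme this follows counts the center
   cell, and the `include_self` flag exposes both conventions. Note that
   self-inclusion couples a cell's own type to its feature vector with
   weight 1/(k+1), which matters for the null calibration discussed below.
2. **Micro-clustering.** Per sample, the composition vectors are
   over-clustered with k-means (squared Euclidean, raw proportions — no
   standardization, though a flag exists) to K = 30 micro-clusters.
   Because no initialization scheme was prescribed, we use seeded
   k-means++ with 10 restarts, keeping the best inertia; empty clusters
   are re-seeded from the point farthest from its center so exactly K
   clusters survive.
3. **Merging.** Micro-clusters are merged into final communities
   (default target 10, the midpoint of the sensible 9–13 range). The
   faithful route is a manual merge map, since in practice an analyst
   inspects the enrichment profile of each micro-cluster. As a
   deterministic automated surrogate we agglomerate micro-cluster
   centroids with average linkage on correlation distance
   (1 − Pearson r between composition profiles) and cut at the target
   count; correlation distance groups clusters by compositional *shape*
   rather than absolute proportions.
4. **Enrichment.** For community c and type t,
   E(c,t) = p(t|c) / p(t) within each sample; E = 1 means no enrichment,
   and types absent from a sample score 0 by the 0/0 convention. The
   cell-count-weighted mean of E(·,t) over communities is identically 1 —
   this algebraic invariant is asserted property-style in the tests.
   Communities are named by their up-to-two types with E ≥ 1.5, in
   descending order, defaulting to "Mixed".
5. **Distances.** For query cells (e.g. each tumor state) the nearest
   distance to each target type is computed per sample, excluding the
   query cell itself when it belongs to the target type. Distances are
   computed in pixels and converted once — `distance_um = distance_px / γ`
   with γ = 2.65 px/µm — so no double rounding occurs. "Unknown" cells
   are excluded from target pools by default (flag available); in
   neighborhoods they are included as an ordinary type by default, since
   cell-typing pipelines legitimately emit that label.
6. **Group comparison.** Community compositions are compared with the
   Kruskal-Wallis rank test (tie-corrected H, χ² approximation with
   groups − 1 degrees of freedom). All-identical pooled values yield
   H = 0, p = 1 rather than an error. The χ² approximation is validated
   against a permutation oracle in the tests.
7. **Signature scoring.** Spot counts are library-size normalized
   (per-spot total scaled to 10⁴, then log1p). This replaces the pinned
   variance-stabilizing transform of the upstream toolchain: module
   scoring only needs a monotone, depth-corrected scale, and the
   normalization used is recorded in the score metadata. The module score
   follows the bin-matched control scheme: genes are ranked by mean
   expression and cut into 24 equal-frequency bins (bin breaks are
   quantiles with duplicates collapsed, so tied averages share a bin and
   the binning is invariant to column order); each signature gene draws
   100 control genes from its bin (seeded, without replacement, signature
   genes excluded; a too-small bin falls back to sampling with
   replacement, with a warning); the spot score is mean(signature) −
   mean(pooled controls). With n_bins = 1 and the full control pool this
   reduces exactly to mean(signature) − mean(all other genes), which the
   tests assert to 1e-9. "High" spots are those at or above the
   (100 − top_pct) percentile (default top 10%) of the sample's scores —
   the ≥ convention means fully tied scores flag every spot, which is
   documented rather than special-cased — and the per-cluster percentage
   of high spots is the machine twin of the bar-plot quantification.
   The percentile is computed per sample, matching per-section scoring.

# Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `k_neighbors` | 100 | cells | neighborhood window matching the myeloid/tumor microstructure scale |
| `n_microclusters` (K) | 30 | clusters | deliberate over-clustering before merging |
| `n_communities` | 10 | communities | midpoint of the sensible 9–13 range |
| `px_per_um` (γ) | 2.65 | px/µm | imaging-instrument calibration |
| `top_pct` | 10 | % | top-decile definition of "high" signature spots |
| `n_bins` / `n_ctrl` | 24 / 100 | — | conventional defaults of the bin-matched scoring scheme |

# The synthetic world

The generator exists so that every downstream stage has ground truth; its
defaults are a fixed "stated world", not knobs.

* **Geometry** (`bcc_preset_regions()`): a 2000 × 2000 px canvas at 0.005
  cells/px² (≈ 20,000 cells, a realistic whole-slide cell count at this
  crop) with background stroma, a 600 px tumor nodule, a 300 px
  stroma-deplete BST-like core inside it, a 250 px myeloid strip along the
  top edge, and a 250 px BIT-like band directly abutting the strip. By
  construction every BIT-band cell is nearer the strip than any BST-core
  cell, so the qualitative distance contrast is planted, not assumed.
  No quantitative niche geometry was available to emulate; these values
  were chosen once to make the recovery tests well-posed and are not
  revisited.
* **Placement**: homogeneous Poisson per region (count ~ Poisson(density ×
  area), uniform positions), with later regions overriding earlier ones
  where they overlap — a cell inside both nodule and core belongs to the
  core, and the override also discards earlier-region points there so
  overlap density equals the later region's density.
* **Types**: each region draws one mixture from a Dirichlet over the
  17-type vocabulary and cells sample types i.i.d. from it. Dominant
  concentrations are large (≈ 50–70) so regions are compositionally
  well-separated; the tail concentration for unlisted types is 0.05 in
  stroma-adjacent regions and 0.01 inside the two tumor-nest regions,
  reflecting that solid tumor nests and the stroma-deplete core exclude
  other populations — and ensuring the planted geometry, not stray type
  draws, determines nearest-myeloid distances.
* **Spots** (`generate_spots()`): a regular grid at 100 µm pitch / 55 µm
  diameter (the standard Visium layout), negative-binomial counts with
  shared dispersion 0.5 around a baseline mean of 5, and the 16-gene
  signature's mean multiplied by exp(δ) (default δ = 2) inside the BIT
  band. Spot cluster labels are the region of the spot center.

What the generator does **not** emulate: segmentation error, cell-size and
density gradients, marker spillover, spatially varying library size,
cell-type-specific expression programs outside the planted signature, and
irregular tissue boundaries. A green recovery test therefore establishes
that the pipeline recovers planted compositional niches under idealized
noise — not that it would resolve every niche in real tissue.

# Numerical choices

* k-NN and nearest-type distances use exact O(n²) brute-force kernels in
  C++ with (distance, index) lexicographic tie-breaks — deterministic and
  oracle-verifiable, and ~seconds at n = 20,000; approximate trees would
  buy nothing at whole-slide scale here.
* k-means runs on doubles with Lloyd updates to a fixed-point of the
  assignment (max 100 iterations); determinism comes from the seeded
  k-means++ draw, not from convergence order.
* Correlation distance on centroids handles constant profiles by treating
  undefined correlations as 0 (distance 1).
* The ≥-threshold and quantile type 7 fix the tie behavior of the
  top-decile rule; 20 distinct scores at top_pct = 10 flag exactly 2.
* Enrichment divisions are guarded by the 0/0 → 0 convention only for
  types absent from the whole sample; empty clusters are dropped (they
  cannot arise from k-means thanks to the farthest-point remedy).

# Known limitations

* The null-tissue enrichment calibration has a statistical floor: with
  K = 30 micro-clusters over 20,000 cells (~667 cells each), even a
  perfectly unstructured tissue shows per-cluster enrichment fluctuations
  of ±0.1–0.3 for types at frequency 0.1–0.5 (binomial sampling alone),
  and self-inclusion adds a mechanical own-type bias on top. Enrichment
  scores of micro-clusters should therefore be read against this floor;
  only community-level scores over thousands of cells are precise at the
  ±0.1 level.
* Auto-merging is a surrogate for expert grouping; when reproducing a
  specific published grouping, supply the manual merge map.
* Communities are clustered per sample; labels are not matched across
  samples.
* The Kruskal-Wallis p-value uses the χ² approximation, adequate at the
  group sizes used here but conservative for very small samples — the
  permutation oracle in the tests bounds the discrepancy.
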