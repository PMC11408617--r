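# spatialniche

Spatial niche detection and gene-signature scoring for multiplexed tissue
imaging and spatial transcriptomics.

## The problem

Multiplexed imaging (e.g. CODEX) of a tumor section yields, after
segmentation and cell typing, a *cell table*: one row per cell with pixel
coordinates and a cell-type label. The biology of interest — for example,
whether a drug-resistant tumor state such as the basal-to-inflammatory
transition (BIT) arises inside a myeloid-dominant inflammatory neighborhood
while the basal-to-squamous transition (BST) sits in a stroma-deplete core —
lives not in single cells but in *spatial communities*: contiguous niches
with a characteristic cell-type composition. `spatialniche` reconstructs
those communities and quantifies them:

1. **Cellular neighborhoods.** For each cell, its k = 100 spatial nearest
   neighbors (Euclidean pixel distance, per sample) are summarized as a
   cell-type proportion vector.
2. **Spatial communities.** Per sample, the neighborhood vectors are
   over-clustered with seeded k-means into K = 30 micro-clusters, which are
   merged (automatically by average-linkage agglomeration on centroid
   correlation distance, or via a user-supplied map) into ~9–13
   communities.
3. **Enrichment scores.** For community *c* and type *t*,
   `E(c,t) = p(t|c) / p(t)`: the type's proportion inside the community over
   its sample-wide proportion. `E = 1` means no enrichment; communities are
   named from their top-enriched types.
4. **Distance statistics.** For chosen query cells (e.g. each tumor state),
   the nearest distance to each target type, converted from pixels to
   micrometers with a calibration of 2.65 px/µm, plus a tie-corrected
   Kruskal-Wallis test for group comparisons.
5. **Signature scoring.** For Visium-style spot matrices, gene-module
   scores with expression-bin-matched control genes (24 bins, 100 controls
   per signature gene), and the percentage of top-decile spots per cluster.

A synthetic-tissue module plants known niches (Poisson cell placement in
parametric regions with Dirichlet type mixtures; negative-binomial spot
counts with a log-fold signature uplift) so every stage can be validated
against ground truth.

## Worked example

```r
library(spatialniche)

# ~20,000 cells, five planted regions: stroma, tumor nodule, BST core,
# myeloid strip, BIT band abutting the strip
sim <- generate_tissue(bcc_preset_regions(), seed = 1)

comp  <- composition_vectors(knn_neighbors(sim$cells, k = 100), sim$cells)
micro <- cluster_compositions(comp, sim$cells, K = 30, seed = 1)
comm  <- merge_microclusters(micro, sim$cells, "auto", n_communities = 5)

adjusted_rand_index(comm$community, sim$truth$region)
#> [1] 0.8688602

dt <- nearest_type_distance(sim$cells, c("BIT tumor", "BST tumor"),
                            "Macrophage", px_per_um = 2.65)
summarize_distances(dt)$summary
#>       group target_type    n    mean_um median_um
#> 1 BIT tumor  Macrophage 1712   7.275882   6.80375
#> 2 BST tumor  Macrophage 1262 323.898656 325.51364
```

The recovered communities match the planted regions (adjusted Rand index
0.87), and BIT-state tumor cells sit ~7 µm from the nearest macrophage
versus ~324 µm for BST-core cells — the pipeline recovers the planted
"BIT lives in a myeloid niche" architecture. Signature scoring works the
same way on synthetic spots:

```r
spec <- spot_gen_spec(delta = 2)                 # 16-gene planted uplift
sp   <- generate_spots(spec, bcc_preset_regions(), seed = 1)
sc   <- module_score(normalize_log(sp), spec$signature, seed = 1)
high_fraction_by_cluster(sc, sp$cluster, top_pct = 10)
```

A command-line interface mirrors the R API
(`Rscript inst/cli/spatialniche.R simulate|neighborhoods|communities|distances|score|report ...`).

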