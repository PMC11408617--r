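# build a composition matrix directly (bypassing knn) for k-means unit tests
fake_comp <- function(mat, cells) {
  structure(mat, k = 1L, include_self = FALSE,
            dimnames = list(cells$cell_id, cell_vocabulary(cells)$types),
            class = c("neighborhood_composition", "matrix", "array"))
}

test_that("k-means over-clustering: K = 1 and separable blobs", {
  vocab <- type_vocabulary(c("A", "B"))
  cells <- make_cells(runif(100), runif(100),
                      rep(c("A", "B"), c(60, 40)), vocab = vocab)
  comp <- fake_comp(cbind(rep(c(1, 0), c(60, 40)), rep(c(0, 1), c(60, 40))),
                    cells)
  one <- cluster_compositions(comp, cells, K = 1, seed = 1)
  expect_true(all(one$cluster == 1L))
  expect_equal(one$centroids$s1[1, ], colMeans(comp), ignore_attr = TRUE)

  two <- cluster_compositions(comp, cells, K = 2, seed = 1)
  expect_equal(length(unique(two$cluster[1:60])), 1L)
  expect_equal(length(unique(two$cluster[61:100])), 1L)
  expect_false(two$cluster[1] == two$cluster[61])
  cen <- two$centroids$s1[order(two$centroids$s1[, "A"], decreasing = TRUE), ]
  expect_equal(unname(cen), rbind(c(1, 0), c(0, 1)))

  expect_error(cluster_compositions(comp, cells, K = 101, seed = 1), "exceeds")
})

test_that("clustering is deterministic given the seed", {
  sim <- small_preset(density = 5e-4, seed = 2)
  comp <- composition_vectors(knn_neighbors(sim$cells, 15), sim$cells)
  a <- cluster_compositions(comp, sim$cells, K = 8, seed = 7)
  b <- cluster_compositions(comp, sim$cells, K = 8, seed = 7)
  expect_identical(a$cluster, b$cluster)
  expect_identical(a$centroids, b$centroids)
})

test_that("enrichment scores follow the ratio definition", {
  vocab <- type_vocabulary(c("A", "B", "C"))
  cells <- make_cells(1:10, 1:10, rep(c("A", "B"), c(6, 4)), vocab = vocab)
  # single cluster -> E = 1 for present types, 0 for absent
  E1 <- enrichment_scores(rep(1L, 10), cells)$s1
  expect_equal(unname(E1[1, ]), c(1, 1, 0))

  # cluster 1 = {4 A, 1 B}: E(1,A) = (4/5)/(6/10), E(1,B) = (1/5)/(4/10)
  lab <- c(1, 1, 1, 1, 2, 2, 1, 2, 2, 2)
  E <- enrichment_scores(lab, cells)$s1
  expect_equal(E["1", "A"], (4 / 5) / (6 / 10))
  expect_equal(E["1", "B"], 0.5)
})

test_that("weighted-mean normalization of enrichment holds on any input", {
  for (seed in 1:5) {
    cells <- random_cells(500, types = c("A", "B", "C", "D"), seed = seed)
    lab <- sample(1:7, 500, replace = TRUE)
    E <- enrichment_scores(lab, cells)$s1
    sizes <- as.numeric(table(lab)[rownames(E)])
    present <- colSums(E) > 0
    wmean <- colSums(E * sizes) / sum(sizes)
    expect_equal(unname(wmean[present]), rep(1, sum(present)),
                 tolerance = 1e-9)
  }
})

test_that("merging coarsens the partition and respects the map", {
  sim <- small_preset(density = 5e-4, seed = 4)
  cells <- sim$cells
  comp <- composition_vectors(knn_neighbors(cells, 15), cells)
  micro <- cluster_compositions(comp, cells, K = 10, seed = 1)

  ident <- merge_microclusters(micro, cells, "manual",
                               merge_map = setNames(as.character(1:10), 1:10))
  expect_equal(as.integer(ident$community), micro$cluster)

  auto <- merge_microclusters(micro, cells, "auto", n_communities = 4)
  # coarsening: cells sharing a micro-cluster always share a community
  split_map <- tapply(auto$community, micro$cluster, function(v) length(unique(v)))
  expect_true(all(split_map == 1))

  expect_error(merge_microclusters(micro, cells, "manual",
                                   merge_map = setNames("x", "1")),
               "not total")
  expect_error(merge_microclusters(micro, cells, "auto", n_communities = 1),
               "\\[2, K\\]")
})

test_that("identical centroids merge first under the auto strategy", {
  vocab <- type_vocabulary(c("A", "B", "C"))
  # 3 blobs of one-hot compositions; blobs 1 and 2 identical
  cells <- make_cells(seq_len(90), rep(1, 90),
                      rep("A", 90), vocab = vocab)
  mat <- rbind(matrix(rep(c(1, 0, 0), 30), ncol = 3, byrow = TRUE),
               matrix(rep(c(1, 0, 0), 30), ncol = 3, byrow = TRUE),
               matrix(rep(c(0, 1, 0), 30), ncol = 3, byrow = TRUE))
  comp <- fake_comp(mat, cells)
  micro <- cluster_compositions(comp, cells, K = 3, seed = 2)
  merged <- merge_microclusters(micro, cells, "auto", n_communities = 2)
  # the two identical-centroid micro-clusters land in the same community
  cen <- micro$centroids$s1
  same <- which(cen[, "A"] > 0.5)
  expect_equal(length(unique(merged$merge_map$s1[same])), 1L)
})

test_that("community naming follows the top-m threshold rule", {
  E <- rbind(c(Fibroblast = 5, Tumor = 0.8, Macrophage = 0.4),
             c(Fibroblast = 1, Tumor = 1, Macrophage = 1),
             c(Fibroblast = 1.6, Tumor = 2.9, Macrophage = 1.7))
  rownames(E) <- 1:3
  nm <- name_communities(E)
  expect_equal(unname(nm), c("Fibroblast", "Mixed", "Tumor / Macrophage"))
  expect_equal(unname(name_communities(E, m = 1)[3]), "Tumor")
})

test_that("adjusted Rand index behaves on known partitions", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
  expect_equal(adjusted_rand_index(rep(1, 6), rep(1, 6)), 1)
  set.seed(1)
  a <- sample(1:3, 3000, replace = TRUE)
  b <- sample(1:3, 3000, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.02)  # independent ~ 0
})
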