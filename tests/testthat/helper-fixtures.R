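# shared fixture builders; everything is generated in code

# small hand-positioned cell table: coordinates and types fully controlled
make_cells <- function(x, y, type, sample = "s1", vocab = NULL) {
  cell_table(sample_id = rep(sample, length.out = length(x)),
             cell_id = sprintf("c%03d", seq_along(x)),
             x_px = x, y_px = y, cell_type = type, vocabulary = vocab)
}

# uniform random cells with i.i.d. types, for oracle comparisons
random_cells <- function(n, types = c("A", "B", "C"), seed = 1,
                         canvas = c(1000, 1000), sample = "s1") {
  set.seed(seed)
  make_cells(runif(n, 0, canvas[1]), runif(n, 0, canvas[2]),
             sample(types, n, replace = TRUE), sample = sample)
}

# quadratic-time k-NN oracle: full distance matrix, sort by (distance, index)
knn_oracle <- function(cells, k) {
  n <- nrow(cells)
  idx <- matrix(NA_integer_, n, k)
  dst <- matrix(NA_real_, n, k)
  for (s in unique(cells$sample_id)) {
    rows <- which(cells$sample_id == s)
    D <- as.matrix(dist(cbind(cells$x_px[rows], cells$y_px[rows])))
    for (a in seq_along(rows)) {
      d <- D[a, ]
      d[a] <- Inf
      ord <- order(d, seq_along(d))[seq_len(k)]
      idx[rows[a], ] <- rows[ord]
      dst[rows[a], ] <- d[ord]
    }
  }
  list(idx = idx, dist = dst)
}

# quadratic nearest-type-distance oracle
nearest_oracle <- function(cells, qrows, target_type) {
  vapply(qrows, function(i) {
    trows <- which(cells$sample_id == cells$sample_id[i] &
                     cells$cell_type == target_type)
    trows <- setdiff(trows, i)
    if (length(trows) == 0L) return(NA_real_)
    min(sqrt((cells$x_px[trows] - cells$x_px[i])^2 +
               (cells$y_px[trows] - cells$y_px[i])^2))
  }, numeric(1))
}

# small planted-region tissue: cheap stand-in for the full preset
small_preset <- function(density = 0.002, seed = 7) {
  generate_tissue(bcc_preset_regions(density = density), seed = seed)
}
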