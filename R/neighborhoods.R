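#' k-nearest-neighbor index per cell
#'
#' For every cell, its k nearest other cells of the same sample under
#' Euclidean pixel distance.  Neighbors never cross sample boundaries; the
#' index cell is excluded from its own list; entries are sorted by ascending
#' distance with ties broken by ascending row index, so the result is fully
#' deterministic.
#'
#' @param cells a [cell_table()].
#' @param k neighborhood size (default 100).  Every sample must hold at
#'   least `k + 1` cells.
#' @return An object of class `neighbor_index`: list with `idx` and `dist`
#'   (n x k matrices; `idx` holds 1-based row indices into `cells`), and `k`.
#' @export
knn_neighbors <- function(cells, k = 100L) {
  stopifnot(inherits(cells, "cell_table"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be a positive integer")
  n <- nrow(cells)
  idx <- matrix(NA_integer_, n, k)
  dst <- matrix(NA_real_, n, k)
  for (s in unique(cells$sample_id)) {
    rows <- which(cells$sample_id == s)
    if (length(rows) <= k)
      stop("sample \"", s, "\" has ", length(rows),
           " cells; k = ", k, " requires at least ", k + 1L)
    res <- .knn_brute_cpp(cells$x_px[rows], cells$y_px[rows], k)
    idx[rows, ] <- matrix(rows[res$idx], length(rows), k)
    dst[rows, ] <- res$dist
  }
  structure(list(idx = idx, dist = dst, k = k), class = "neighbor_index")
}

#' Neighborhood cell-type composition vectors
#'
#' Summarizes each cell's neighborhood as the proportion of every vocabulary
#' type among its members.  With `include_self = TRUE` (default) the window
#' holds k + 1 cells (the index cell plus its k neighbors); with `FALSE`,
#' the k neighbors only.  Each row is non-negative and sums to 1.
#'
#' @param index a `neighbor_index` built from `cells`.
#' @param cells the same [cell_table()] the index was built from.
#' @param include_self count the index cell itself in its own window?
#' @return An n x n_types matrix of class `neighborhood_composition` with
#'   the vocabulary types as column names and attributes `k`, `include_self`.
#' @export
composition_vectors <- function(index, cells, include_self = TRUE) {
  stopifnot(inherits(index, "neighbor_index"), inherits(cells, "cell_table"))
  if (nrow(index$idx) != nrow(cells))
    stop("index and cell table sizes differ")
  types <- cell_vocabulary(cells)$types
  tcode <- match(cells$cell_type, types)
  n <- nrow(cells)
  k <- index$k
  # tabulate neighbor types row-wise without materializing a table object:
  # combined code (type - 1) * n + row indexes an n x n_types count matrix
  row_of <- rep.int(seq_len(n), k)
  type_of <- tcode[as.vector(index$idx)]
  counts <- tabulate((type_of - 1L) * n + row_of, nbins = n * length(types))
  comp <- matrix(as.numeric(counts), n, length(types),
                 dimnames = list(cells$cell_id, types))
  denom <- k
  if (include_self) {
    comp[cbind(seq_len(n), tcode)] <- comp[cbind(seq_len(n), tcode)] + 1
    denom <- k + 1
  }
  comp <- comp / denom
  structure(comp, k = k, include_self = include_self,
            class = c("neighborhood_composition", "matrix", "array"))
}
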