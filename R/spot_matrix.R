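#' Construct a spot matrix
#'
#' A spot matrix is a Visium-style container: a spots x genes matrix of
#' non-negative integer counts, per-spot x/y coordinates (same pixel
#' convention as the cell table), and an optional per-spot cluster label.
#'
#' @param counts numeric matrix (spots in rows, genes in columns) or a sparse
#'   `Matrix`; coerced to a dense base matrix.
#' @param spot_id,gene unique identifiers for rows and columns; taken from
#'   dimnames when `NULL`.
#' @param x_px,y_px spot-center coordinates in pixels.
#' @param cluster optional per-spot cluster labels.
#' @return An object of class `spot_matrix`: a list with elements `counts`
#'   (dense integer matrix with dimnames), `coords` (data.frame) and
#'   `cluster` (character or `NULL`).
#' @export
spot_matrix <- function(counts, spot_id = NULL, gene = NULL,
                        x_px = NULL, y_px = NULL, cluster = NULL) {
  counts <- as.matrix(counts)
  if (is.null(spot_id)) spot_id <- rownames(counts)
  if (is.null(gene)) gene <- colnames(counts)
  if (is.null(spot_id) || is.null(gene))
    stop("spot and gene identifiers are required")
  spot_id <- as.character(spot_id); gene <- as.character(gene)
  if (length(spot_id) != nrow(counts) || length(gene) != ncol(counts))
    stop("identifier length (", length(spot_id), " spots, ", length(gene),
         " genes) does not match matrix shape (", nrow(counts), " x ",
         ncol(counts), ")")
  if (anyDuplicated(spot_id)) stop("duplicate spot identifiers")
  if (anyDuplicated(gene)) stop("duplicate gene names")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(spot_id, gene)
  if (is.null(x_px)) x_px <- rep(NA_real_, length(spot_id))
  if (is.null(y_px)) y_px <- rep(NA_real_, length(spot_id))
  coords <- data.frame(spot_id = spot_id, x_px = as.numeric(x_px),
                       y_px = as.numeric(y_px), stringsAsFactors = FALSE)
  if (!is.null(cluster)) {
    cluster <- as.character(cluster)
    if (length(cluster) != length(spot_id))
      stop("cluster labels must cover every spot")
  }
  structure(list(counts = counts, coords = coords, cluster = cluster),
            class = "spot_matrix")
}

#' @export
print.spot_matrix <- function(x, ...) {
  cat("spot_matrix:", nrow(x$counts), "spots x", ncol(x$counts), "genes",
      if (!is.null(x$cluster)) paste0("(", length(unique(x$cluster)), " clusters)"),
      "\n")
  invisible(x)
}

#' Read a spot matrix from MatrixMarket or dense delimited text
#'
#' Two layouts are supported.  Sparse: `path` is a MatrixMarket `.mtx` file
#' with genes in rows and spots in columns (the Visium export convention),
#' accompanied by `genes_path` and `spots_path` sidecars holding one
#' identifier per line.  Dense: `path` is a delimited file with spot ids in
#' the first column and gene names in the header, and the sidecars are
#' omitted.
#'
#' @param path matrix file (`.mtx` for sparse, otherwise dense text).
#' @param genes_path,spots_path identifier sidecars (sparse layout only).
#' @param coords_path optional delimited sidecar with columns
#'   `spot_id, x, y`.
#' @param cluster_path optional delimited sidecar with columns
#'   `spot_id, cluster`.
#' @param sep separator for dense matrix and sidecar tables.
#' @return A `spot_matrix`.
#' @export
read_spot_matrix <- function(path, genes_path = NULL, spots_path = NULL,
                             coords_path = NULL, cluster_path = NULL,
                             sep = ",") {
  if (grepl("\\.mtx$", path)) {
    if (is.null(genes_path) || is.null(spots_path))
      stop("sparse layout requires genes_path and spots_path sidecars")
    m <- Matrix::readMM(path)  # genes x spots
    genes <- readLines(genes_path)
    spots <- readLines(spots_path)
    if (nrow(m) != length(genes) || ncol(m) != length(spots))
      stop("matrix shape (", nrow(m), " x ", ncol(m),
           ") does not match sidecars (", length(genes), " genes, ",
           length(spots), " spots)")
    counts <- t(as.matrix(m))
    dimnames(counts) <- list(spots, genes)
  } else {
    tab <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    counts <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(counts) <- as.character(tab[[1L]])
    spots <- rownames(counts)
  }
  x <- y <- cluster <- NULL
  if (!is.null(coords_path)) {
    co <- read.delim(coords_path, sep = sep, header = TRUE,
                     stringsAsFactors = FALSE)
    idx <- match(spots, as.character(co$spot_id))
    if (anyNA(idx)) stop("coords sidecar is missing spots")
    x <- co$x[idx]; y <- co$y[idx]
  }
  if (!is.null(cluster_path)) {
    cl <- read.delim(cluster_path, sep = sep, header = TRUE,
                     colClasses = "character", stringsAsFactors = FALSE)
    idx <- match(spots, cl$spot_id)
    if (anyNA(idx)) stop("cluster sidecar is missing spots")
    cluster <- cl$cluster[idx]
  }
  spot_matrix(counts, x_px = x, y_px = y, cluster = cluster)
}

#' Write a spot matrix in the sparse MatrixMarket layout
#'
#' Emits `<stem>.mtx` (genes x spots), `<stem>.genes.txt`,
#' `<stem>.spots.txt`, `<stem>.coords.csv`, and, when cluster labels exist,
#' `<stem>.clusters.csv`, matching what [read_spot_matrix()] consumes.
#'
#' @param spots a `spot_matrix`.
#' @param stem output path stem (no extension).
#' @return Named character vector of the files written, invisibly.
#' @export
write_spot_matrix <- function(spots, stem) {
  stopifnot(inherits(spots, "spot_matrix"))
  paths <- c(mtx = paste0(stem, ".mtx"), genes = paste0(stem, ".genes.txt"),
             spots = paste0(stem, ".spots.txt"),
             coords = paste0(stem, ".coords.csv"))
  Matrix::writeMM(Matrix::Matrix(t(spots$counts), sparse = TRUE), paths["mtx"])
  writeLines(colnames(spots$counts), paths["genes"])
  writeLines(rownames(spots$counts), paths["spots"])
  co <- spots$coords
  names(co) <- c("spot_id", "x", "y")
  write.table(co, paths["coords"], sep = ",", quote = FALSE, row.names = FALSE)
  if (!is.null(spots$cluster)) {
    paths["clusters"] <- paste0(stem, ".clusters.csv")
    write.table(data.frame(spot_id = rownames(spots$counts),
                           cluster = spots$cluster),
                paths["clusters"], sep = ",", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
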