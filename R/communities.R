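# seeded k-means++ initialization over rows of X
.kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centers <- integer(K)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((X - matrix(X[centers[1L], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(K - 1L)) {
    if (all(d2 == 0)) {
      centers[j + 1L] <- sample.int(n, 1L)
    } else {
      centers[j + 1L] <- sample.int(n, 1L, prob = d2)
    }
    dn <- rowSums((X - matrix(X[centers[j + 1L], ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, dn)
  }
  X[centers, , drop = FALSE]
}

# Lloyd iterations with empty clusters re-seeded from the farthest point
.lloyd <- function(X, centers, max_iter = 100L) {
  n <- nrow(X); K <- nrow(centers)
  xsq <- rowSums(X^2)
  assign_prev <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- outer(xsq, rowSums(centers^2), "+") - 2 * X %*% t(centers)
    assign_cur <- max.col(-d2, ties.method = "first")
    mind2 <- d2[cbind(seq_len(n), assign_cur)]
    for (j in seq_len(K)) {          # farthest-point remedy for empty clusters
      if (!any(assign_cur == j)) {
        far <- which.max(mind2)
        assign_cur[far] <- j
        mind2[far] <- 0
      }
    }
    if (identical(assign_cur, assign_prev)) break
    assign_prev <- assign_cur
    for (j in seq_len(K))
      centers[j, ] <- colMeans(X[assign_cur == j, , drop = FALSE])
  }
  d2 <- outer(xsq, rowSums(centers^2), "+") - 2 * X %*% t(centers)
  inertia <- sum(pmax(d2[cbind(seq_len(n), assign_cur)], 0))
  list(cluster = assign_cur, centers = centers, inertia = inertia)
}

#' Micro-cluster neighborhood compositions with seeded k-means
#'
#' Per-sample k-means (squared Euclidean, Lloyd iterations) on the raw
#' composition vectors, over-clustering to K micro-clusters.  Initialization
#' is seeded k-means++; the best of `n_restarts` runs by within-cluster sum
#' of squares is kept, so results are deterministic given `seed`.  Empty
#' clusters are re-seeded from the point farthest from its center, keeping
#' exactly K clusters.
#'
#' @param comp a `neighborhood_composition` matrix from
#'   [composition_vectors()].
#' @param cells the matching [cell_table()] (provides sample membership).
#' @param K number of micro-clusters per sample (default 30).
#' @param seed integer RNG seed.
#' @param n_restarts independent k-means++ starts (default 10).
#' @param standardize z-score the composition columns first (off by
#'   default: the pipeline clusters raw proportions).
#' @return An object of class `microcluster_assignment`: list with `cluster`
#'   (per-cell id in 1..K), `centroids` (per sample: K x n_types matrix on
#'   the original proportion scale), `K`, `seed`, `n_restarts`.
#' @export
cluster_compositions <- function(comp, cells, K = 30L, seed = 1L,
                                 n_restarts = 10L, standardize = FALSE) {
  stopifnot(inherits(comp, "neighborhood_composition"),
            inherits(cells, "cell_table"), nrow(comp) == nrow(cells))
  K <- as.integer(K)
  cluster <- integer(nrow(cells))
  centroids <- list()
  for (s in unique(cells$sample_id)) {
    rows <- which(cells$sample_id == s)
    if (length(rows) < K)
      stop("sample \"", s, "\": K = ", K, " exceeds cell count ", length(rows))
    X <- comp[rows, , drop = FALSE]  # subsetting drops the composition class
    if (standardize) {
      sds <- apply(X, 2L, stats::sd)
      sds[sds == 0] <- 1
      X <- scale(X, center = TRUE, scale = sds)
    }
    set.seed(seed)
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- .lloyd(X, .kmeanspp_init(X, K))
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
    cluster[rows] <- best$cluster
    # centroids reported as mean raw compositions (valid proportion vectors)
    cen <- matrix(0, K, ncol(comp), dimnames = list(NULL, colnames(comp)))
    for (j in seq_len(K))
      cen[j, ] <- colMeans(comp[rows[best$cluster == j], , drop = FALSE])
    centroids[[s]] <- cen
  }
  structure(list(cluster = cluster, centroids = centroids, K = K,
                 seed = as.integer(seed), n_restarts = as.integer(n_restarts)),
            class = "microcluster_assignment")
}

#' Cell-type enrichment scores per cluster
#'
#' For each sample, the enrichment of type t in cluster c is
#' `E(c, t) = p(t | c) / p(t)`: the type's proportion among the cluster's
#' cells over its proportion among all the sample's cells.  1 means no
#' enrichment; types absent from the whole sample score 0 by the 0/0
#' convention.  For every type present in a sample, the cell-count-weighted
#' mean of `E(., t)` over clusters is exactly 1.
#'
#' @param assignment per-cell cluster labels (integer or character vector),
#'   or a `microcluster_assignment` / `community_assignment` object.
#' @param cells the matching [cell_table()].
#' @return A list of class `enrichment_matrix`, one cluster x type matrix
#'   per sample (empty clusters are dropped with a warning).
#' @export
enrichment_scores <- function(assignment, cells) {
  labels <- .assignment_labels(assignment, cells)
  types <- cell_vocabulary(cells)$types
  out <- list()
  for (s in unique(cells$sample_id)) {
    rows <- cells$sample_id == s
    lab <- labels[rows]
    ty <- factor(cells$cell_type[rows], levels = types)
    overall <- as.numeric(prop.table(table(ty)))
    lv <- sort(unique(lab))
    E <- matrix(0, length(lv), length(types), dimnames = list(as.character(lv), types))
    for (i in seq_along(lv)) {
      within <- as.numeric(prop.table(table(ty[lab == lv[i]])))
      ratio <- ifelse(overall > 0, within / overall, 0)
      E[i, ] <- ratio
    }
    out[[s]] <- E
  }
  structure(out, class = "enrichment_matrix")
}

# accept raw label vectors or assignment objects
.assignment_labels <- function(assignment, cells) {
  if (inherits(assignment, "microcluster_assignment")) return(assignment$cluster)
  if (inherits(assignment, "community_assignment")) return(assignment$community)
  if (length(assignment) != nrow(cells))
    stop("assignment must cover every cell")
  assignment
}

#' Merge micro-clusters into spatial communities
#'
#' Either applies a user-supplied merge map verbatim (`strategy = "manual"`,
#' the faithful route when an analyst has grouped micro-clusters by eye), or
#' agglomerates micro-cluster centroid composition vectors with average
#' linkage on correlation distance and cuts the tree at the target community
#' count (`strategy = "auto"`).  Merging only ever coarsens the partition:
#' cells sharing a micro-cluster always share a community.
#'
#' @param assignment a `microcluster_assignment`.
#' @param cells the matching [cell_table()].
#' @param strategy `"auto"` or `"manual"`.
#' @param n_communities target community count for `"auto"` (default 10);
#'   must lie in `[2, K]`.
#' @param merge_map for `"manual"`: named integer/character vector mapping
#'   every micro-cluster id `1..K` to a community label; must be total.
#' @return An object of class `community_assignment`: list with `community`
#'   (per-cell label), `merge_map` (per sample, micro-cluster -> community),
#'   and `n_communities`.
#' @export
merge_microclusters <- function(assignment, cells,
                                strategy = c("auto", "manual"),
                                n_communities = 10L, merge_map = NULL) {
  stopifnot(inherits(assignment, "microcluster_assignment"),
            inherits(cells, "cell_table"))
  strategy <- match.arg(strategy)
  K <- assignment$K
  maps <- list()
  community <- character(nrow(cells))
  for (s in unique(cells$sample_id)) {
    rows <- cells$sample_id == s
    if (strategy == "manual") {
      if (is.null(merge_map)) stop("manual strategy requires merge_map")
      mm <- merge_map
      if (is.null(names(mm))) names(mm) <- seq_along(mm)
      missing_mc <- setdiff(as.character(seq_len(K)), names(mm))
      if (length(missing_mc))
        stop("merge map is not total: micro-cluster(s) ",
             paste(missing_mc, collapse = ", "), " unmapped")
      map <- as.character(mm)[match(as.character(seq_len(K)), names(mm))]
    } else {
      n_communities <- as.integer(n_communities)
      if (n_communities < 2L || n_communities > K)
        stop("auto merge target must lie in [2, K]")
      cen <- assignment$centroids[[s]]
      # correlation distance between centroid composition profiles; constant
      # profiles (zero variance) get distance 1 to everything
      cc <- suppressWarnings(cor(t(cen)))
      cc[!is.finite(cc)] <- 0
      d <- as.dist(1 - cc)
      hc <- hclust(d, method = "average")
      map <- as.character(cutree(hc, k = n_communities))
    }
    community[rows] <- map[assignment$cluster[rows]]
    maps[[s]] <- setNames(map, seq_len(K))
  }
  structure(list(community = community, merge_map = maps,
                 n_communities = length(unique(community))),
            class = "community_assignment")
}

#' Name communities from their enrichment profiles
#'
#' A community is named by concatenating (with `" / "`) up to `m` cell types
#' whose enrichment score reaches `threshold`, ordered by descending score;
#' communities where no type passes are named `"Mixed"`.
#'
#' @param enrichment an `enrichment_matrix` (or one of its per-sample
#'   matrices).
#' @param m maximum number of types in a name (default 2).
#' @param threshold minimum enrichment to contribute to the name
#'   (default 1.5).
#' @return Per sample, a named character vector community id -> name (a
#'   plain vector when a single matrix was supplied).
#' @export
name_communities <- function(enrichment, m = 2L, threshold = 1.5) {
  name_one <- function(E) {
    out <- character(nrow(E))
    for (i in seq_len(nrow(E))) {
      row <- E[i, ]                     # keeps names even when one type passes
      sc <- sort(row[row >= threshold], decreasing = TRUE)
      out[i] <- if (length(sc) == 0L) "Mixed" else
        paste(names(sc)[seq_len(min(m, length(sc)))], collapse = " / ")
    }
    setNames(out, rownames(E))
  }
  if (is.matrix(enrichment)) return(name_one(enrichment))
  lapply(unclass(enrichment), name_one)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to label names), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return The ARI as a single number.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)     # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}
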