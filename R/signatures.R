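#' Library-size normalization with log transform
#'
#' Scales each spot's counts so its total equals `scale_total` (default
#' 1e4), then applies `log(1 + x)`.  Spots with zero total stay all-zero
#' with a warning.  The transform is invariant to multiplying a spot's
#' counts by a constant, which is all the downstream module score requires:
#' a monotone, depth-corrected expression scale.
#'
#' @param spots a [spot_matrix()] or a plain counts matrix (spots x genes).
#' @param scale_total target per-spot total after scaling.
#' @return A spots x genes numeric matrix with attribute
#'   `normalization = "lognorm"`.
#' @export
normalize_log <- function(spots, scale_total = 1e4) {
  counts <- if (inherits(spots, "spot_matrix")) spots$counts else as.matrix(spots)
  totals <- rowSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " spot(s) with zero total counts; normalized rows set to 0")
    totals[zero] <- 1
  }
  out <- log1p(counts / totals * scale_total)
  attr(out, "normalization") <- "lognorm"
  out
}

#' Gene-module score with expression-bin-matched control genes
#'
#' Implements the bin-matched control scheme for signature scoring: genes
#' are ranked by mean expression across spots and cut into `n_bins`
#' equal-frequency bins; each signature gene draws `n_ctrl` control genes
#' (seeded, without replacement, signature genes excluded) from its own
#' bin; the score of a spot is the mean expression of the signature genes
#' minus the mean expression of the pooled control draw.  Control genes are
#' pooled with multiplicity, so a gene drawn for two signature genes counts
#' twice.
#'
#' @param expr normalized expression matrix (spots x genes), e.g. from
#'   [normalize_log()].
#' @param signature character vector of signature gene names.  Genes absent
#'   from `expr` are dropped with a warning; all absent is an error.
#' @param n_bins number of equal-frequency expression bins (default 24).
#' @param n_ctrl control genes drawn per signature gene (default 100).  A
#'   bin with fewer eligible genes falls back to sampling with replacement,
#'   with a warning.
#' @param seed integer seed for the control draw.
#' @return A numeric vector of per-spot scores with attribute `meta`
#'   (signature used, n_bins, n_ctrl, seed, normalization tag of `expr`).
#' @export
module_score <- function(expr, signature, n_bins = 24L, n_ctrl = 100L,
                         seed = 1L) {
  expr <- as.matrix(expr)
  if (is.null(colnames(expr))) stop("expression matrix must have gene names")
  n_bins <- as.integer(n_bins); n_ctrl <- as.integer(n_ctrl)
  if (n_bins < 1L || n_ctrl < 1L) stop("n_bins and n_ctrl must be >= 1")
  genes <- colnames(expr)
  missing_genes <- setdiff(signature, genes)
  if (length(missing_genes)) {
    if (length(missing_genes) == length(signature))
      stop("none of the signature genes are present in the matrix")
    warning("dropping signature gene(s) absent from matrix: ",
            paste(missing_genes, collapse = ", "))
    signature <- setdiff(signature, missing_genes)
  }
  avg <- colMeans(expr)
  # equal-frequency bins by average expression.  Breaks are quantiles of the
  # averages with duplicates collapsed, so tied averages always share a bin
  # (a constant matrix is a single bin) and binning is invariant to column
  # order
  breaks <- unique(quantile(avg, probs = seq(0, 1, length.out = n_bins + 1L),
                            type = 7, names = FALSE))
  bin <- findInterval(avg, breaks, all.inside = TRUE)
  is_sig <- genes %in% signature

  set.seed(seed)
  ctrl <- character(0)
  for (gs in sort(signature)) {
    pool <- sort(genes[bin == bin[match(gs, genes)] & !is_sig])
    if (length(pool) == 0L) {
      warning("no eligible control genes in the bin of ", gs, "; skipping")
      next
    }
    if (length(pool) < n_ctrl) {
      warning("bin of ", gs, " has ", length(pool), " eligible controls (< ",
              n_ctrl, "); sampling with replacement")
      ctrl <- c(ctrl, sample(pool, n_ctrl, replace = TRUE))
    } else {
      ctrl <- c(ctrl, sample(pool, n_ctrl, replace = FALSE))
    }
  }
  sig_mean <- rowMeans(expr[, signature, drop = FALSE])
  ctrl_mean <- if (length(ctrl)) rowMeans(expr[, ctrl, drop = FALSE]) else 0
  score <- sig_mean - ctrl_mean
  attr(score, "meta") <- list(signature = signature, n_bins = n_bins,
                              n_ctrl = n_ctrl, seed = as.integer(seed),
                              normalization = attr(expr, "normalization"))
  score
}

#' Percentage of high-scoring spots per cluster
#'
#' Flags the sample-wide top `top_pct` percent of scores (threshold = the
#' `100 - top_pct` percentile; spots with score >= threshold are "high" —
#' with heavy ties every tied spot passes) and reports, per cluster, the
#' percentage of its spots that are high.
#'
#' @param scores numeric per-spot scores (e.g. from [module_score()]).
#' @param cluster per-spot cluster labels covering every scored spot.
#' @param top_pct percentile width (default 10: top decile).
#' @return A `data.frame` with columns `cluster`, `n_spots`, `n_high`,
#'   `percent_high`, plus attribute `threshold`.
#' @export
high_fraction_by_cluster <- function(scores, cluster, top_pct = 10) {
  if (length(scores) != length(cluster))
    stop("cluster labels must cover all scored spots")
  if (top_pct <= 0 || top_pct >= 100) stop("top_pct must lie in (0, 100)")
  thr <- as.numeric(quantile(scores, 1 - top_pct / 100, type = 7))
  high <- scores >= thr
  lv <- sort(unique(as.character(cluster)))
  out <- data.frame(
    cluster = lv,
    n_spots = vapply(lv, function(l) sum(cluster == l), integer(1)),
    n_high = vapply(lv, function(l) sum(high[cluster == l]), integer(1)),
    stringsAsFactors = FALSE)
  out$percent_high <- 100 * out$n_high / out$n_spots
  attr(out, "threshold") <- thr
  rownames(out) <- NULL
  out
}
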