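#' Pipeline configuration
#'
#' Collects every tunable parameter of the niche pipeline with the defaults
#' used throughout: 100 spatial nearest neighbors per cell, over-clustering to
#' 30 micro-clusters, merging to 10 spatial communities (sensible range
#' 9--13), a pixel-to-micrometer calibration of 2.65 px/um, and module-score
#' parameters of 24 expression bins with 100 control genes per signature gene.
#'
#' @param k_neighbors neighborhood size k (positive integer; default 100).
#' @param n_microclusters k-means over-clustering target K (default 30).
#' @param n_communities community count after merging (default 10).
#' @param px_per_um pixels per micrometer, gamma > 0 (default 2.65).
#' @param top_pct percentile width for "high score" spots, 0 < top_pct < 100
#'   (default 10: the top decile).
#' @param n_bins,n_ctrl module-score binning parameters (defaults 24, 100).
#' @param seeds named list of per-stage integer seeds (`simulate`,
#'   `microclusters`, `score`); a single integer is recycled to all stages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(k_neighbors = 100L, n_microclusters = 30L,
                            n_communities = 10L, px_per_um = 2.65,
                            top_pct = 10, n_bins = 24L, n_ctrl = 100L,
                            seeds = list(simulate = 1L, microclusters = 1L,
                                         score = 1L)) {
  if (is.numeric(seeds) && length(seeds) == 1L)
    seeds <- list(simulate = seeds, microclusters = seeds, score = seeds)
  counts <- c(k_neighbors = k_neighbors, n_microclusters = n_microclusters,
              n_communities = n_communities, n_bins = n_bins, n_ctrl = n_ctrl)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("count parameters must be positive integers")
  if (!is.numeric(px_per_um) || px_per_um <= 0) stop("px_per_um must be > 0")
  if (top_pct <= 0 || top_pct >= 100) stop("top_pct must lie in (0, 100)")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 n_microclusters = as.integer(n_microclusters),
                 n_communities = as.integer(n_communities),
                 px_per_um = px_per_um, top_pct = top_pct,
                 n_bins = as.integer(n_bins), n_ctrl = as.integer(n_ctrl),
                 seeds = lapply(seeds, as.integer)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n",
      " k_neighbors     =", x$k_neighbors, "\n",
      " n_microclusters =", x$n_microclusters, "\n",
      " n_communities   =", x$n_communities, "\n",
      " px_per_um       =", x$px_per_um, "\n",
      " top_pct         =", x$top_pct, "\n",
      " n_bins/n_ctrl   =", x$n_bins, "/", x$n_ctrl, "\n",
      " seeds           =", paste(names(x$seeds), unlist(x$seeds),
                                  sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Write a configuration as sectioned key = value text
#'
#' The file format is a minimal INI dialect: `[section]` headers followed by
#' `key = value` lines.  Parameters live in `[pipeline]`; seeds in `[seeds]`.
#'
#' @param config a `pipeline_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  num <- function(v) format(v, digits = 15, scientific = FALSE)
  lines <- c(
    "[pipeline]",
    paste0("k_neighbors = ", config$k_neighbors),
    paste0("n_microclusters = ", config$n_microclusters),
    paste0("n_communities = ", config$n_communities),
    paste0("px_per_um = ", num(config$px_per_um)),
    paste0("top_pct = ", num(config$top_pct)),
    paste0("n_bins = ", config$n_bins),
    paste0("n_ctrl = ", config$n_ctrl),
    "[seeds]",
    paste0(names(config$seeds), " = ", unlist(config$seeds))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration written by [write_config()]
#' @param path path to a sectioned key = value file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- ""
  vals <- list(pipeline = list(), seeds = list())
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop(path, ": malformed line: ", ln)
    vals[[section]][[trimws(kv[1L])]] <- as.numeric(trimws(kv[2L]))
  }
  p <- vals$pipeline
  pipeline_config(k_neighbors = p$k_neighbors,
                  n_microclusters = p$n_microclusters,
                  n_communities = p$n_communities,
                  px_per_um = p$px_per_um, top_pct = p$top_pct,
                  n_bins = p$n_bins, n_ctrl = p$n_ctrl,
                  seeds = lapply(vals$seeds, as.integer))
}
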