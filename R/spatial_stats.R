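#' Nearest distance from query cells to each target cell type
#'
#' For each query cell and each target type, the minimum Euclidean distance
#' to any cell of that type within the same sample.  When the query cell is
#' itself of the target type, it is excluded from the target pool (distance
#' to *another* cell of that type).  Distances are computed in pixels and
#' converted once to micrometers by `distance_um = distance_px / px_per_um`.
#'
#' @param cells a [cell_table()].
#' @param query query cells: either a character vector of cell types, or a
#'   per-cell logical/label specification — a logical vector of length
#'   `nrow(cells)`, or a character vector of per-cell group labels with `NA`
#'   for non-query cells.  Type names select all cells of those types and
#'   use the type as the group label.
#' @param target_types character vector of target cell types.
#' @param px_per_um calibration gamma > 0 (default 2.65).
#' @param include_unknown_targets if `FALSE` (default), the literal type
#'   `"Unknown"` is never used as a target pool even when requested.
#' @return A `data.frame` of class `distance_table` with columns
#'   `sample_id`, `cell_id`, `group`, `target_type`, `distance_px`,
#'   `distance_um`.  A (sample, target) pair with no target cells yields
#'   `NA` distances and a warning.
#' @export
nearest_type_distance <- function(cells, query, target_types,
                                  px_per_um = 2.65,
                                  include_unknown_targets = FALSE) {
  stopifnot(inherits(cells, "cell_table"))
  if (!is.numeric(px_per_um) || px_per_um <= 0) stop("px_per_um must be > 0")
  n <- nrow(cells)
  if (is.logical(query)) {
    stopifnot(length(query) == n)
    group <- ifelse(query, "query", NA_character_)
  } else if (length(query) == n && !all(query %in% cells$cell_type)) {
    group <- as.character(query)           # per-cell group labels
  } else {
    group <- ifelse(cells$cell_type %in% query, cells$cell_type, NA_character_)
  }
  if (!include_unknown_targets) target_types <- setdiff(target_types, "Unknown")
  qrows <- which(!is.na(group))
  if (length(qrows) == 0L) stop("no query cells selected")

  res <- vector("list", length(target_types))
  for (ti in seq_along(target_types)) {
    tt <- target_types[ti]
    d <- rep(NA_real_, length(qrows))
    for (s in unique(cells$sample_id[qrows])) {
      qs <- qrows[cells$sample_id[qrows] == s]
      trows <- which(cells$sample_id == s & cells$cell_type == tt)
      if (length(trows) == 0L) {
        warning("sample \"", s, "\": no cells of target type \"", tt,
                "\"; distances set to NA")
        next
      }
      d[match(qs, qrows)] <- .nearest_dist_cpp(cells$x_px, cells$y_px, qs, trows)
    }
    res[[ti]] <- data.frame(sample_id = cells$sample_id[qrows],
                            cell_id = cells$cell_id[qrows],
                            group = group[qrows],
                            target_type = tt,
                            distance_px = d,
                            distance_um = d / px_per_um,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "px_per_um") <- px_per_um
  class(out) <- c("distance_table", "data.frame")
  out
}

#' Summarize a distance table per query group and target type
#'
#' Pools distances across samples and reports, per (group, target type),
#' the count, mean and median distance in micrometers, plus histogram counts
#' over shared bins (the machine twin of a distance density plot).
#'
#' @param table a `distance_table` from [nearest_type_distance()].
#' @param bins number of histogram bins spanning the pooled finite
#'   distances (default 50).
#' @return A list with `summary` (data.frame: group, target_type, n,
#'   mean_um, median_um) and `density` (data.frame: group, target_type,
#'   bin_lo, bin_hi, count).
#' @export
summarize_distances <- function(table, bins = 50L) {
  stopifnot(inherits(table, "distance_table"), nrow(table) > 0L)
  tab <- table[is.finite(table$distance_um), , drop = FALSE]
  groups <- unique(tab[, c("group", "target_type")])
  brk <- seq(0, max(tab$distance_um) * (1 + 1e-9), length.out = bins + 1L)
  summ <- dens <- list()
  for (i in seq_len(nrow(groups))) {
    sel <- tab$group == groups$group[i] & tab$target_type == groups$target_type[i]
    d <- tab$distance_um[sel]
    summ[[i]] <- data.frame(group = groups$group[i],
                            target_type = groups$target_type[i],
                            n = length(d), mean_um = mean(d),
                            median_um = median(d))
    h <- graphics::hist(d, breaks = brk, plot = FALSE)
    dens[[i]] <- data.frame(group = groups$group[i],
                            target_type = groups$target_type[i],
                            bin_lo = brk[-length(brk)], bin_hi = brk[-1L],
                            count = h$counts)
  }
  list(summary = do.call(rbind, summ), density = do.call(rbind, dens))
}

#' Cell-type percentages per community
#'
#' For each (sample, community), the percentage of member cells belonging to
#' each focus type.  Over the full vocabulary the percentages sum to 100.
#'
#' @param assignment a `community_assignment` (or per-cell label vector).
#' @param cells the matching [cell_table()].
#' @param focus_types types to report; defaults to the full vocabulary.
#' @return A `data.frame` with columns `sample_id`, `community`,
#'   `cell_type`, `percent`, `n_cells` (community size).
#' @export
community_type_proportions <- function(assignment, cells, focus_types = NULL) {
  labels <- .assignment_labels(assignment, cells)
  types <- cell_vocabulary(cells)$types
  if (is.null(focus_types)) focus_types <- types
  bad <- setdiff(focus_types, types)
  if (length(bad)) stop("focus types not in vocabulary: ", paste(bad, collapse = ", "))
  out <- list()
  for (s in unique(cells$sample_id)) {
    rows <- cells$sample_id == s
    for (cm in sort(unique(labels[rows]))) {
      members <- rows & labels == cm
      sz <- sum(members)
      pct <- 100 * vapply(focus_types, function(tt)
        sum(cells$cell_type[members] == tt) / sz, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, community = cm, cell_type = focus_types,
        percent = unname(pct), n_cells = sz, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Kruskal-Wallis rank test
#'
#' Rank-based comparison of two or more groups: H with the standard tie
#' correction and a p-value from the chi-squared approximation with
#' `length(groups) - 1` degrees of freedom.  When all pooled values are
#' identical, H = 0 and p = 1.
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return A list with `statistic` (H), `df`, and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("every group must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  if (anyNA(x)) stop("missing values in groups")
  N <- length(x)
  r <- rank(x)                               # midranks for ties
  g <- rep.int(seq_along(groups), sizes)
  rbar <- tapply(r, g, mean)
  H <- 12 / (N * (N + 1)) * sum(sizes * (rbar - (N + 1) / 2)^2)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (correction > 0) H / correction else 0   # all values identical
  df <- length(groups) - 1L
  p <- if (H == 0) 1 else pchisq(H, df, lower.tail = FALSE)
  list(statistic = H, df = df, p_value = p)
}
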