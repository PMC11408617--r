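#' Run the full community-detection pipeline on a cell table
#'
#' Convenience wrapper chaining [knn_neighbors()], [composition_vectors()],
#' [cluster_compositions()], [enrichment_scores()], [merge_microclusters()]
#' and [name_communities()] with the parameters of a [pipeline_config()].
#'
#' @param cells a [cell_table()].
#' @param config a `pipeline_config`.
#' @param include_self count each cell in its own neighborhood window
#'   (default `TRUE`).
#' @param n_communities override for the merge target (defaults to the
#'   config value).
#' @return A list with `composition`, `microclusters`, `communities`,
#'   `enrichment` (on the merged communities), `names`, and `config`.
#' @export
run_community_pipeline <- function(cells, config = pipeline_config(),
                                   include_self = TRUE,
                                   n_communities = config$n_communities) {
  stopifnot(inherits(config, "pipeline_config"))
  index <- knn_neighbors(cells, k = config$k_neighbors)
  comp <- composition_vectors(index, cells, include_self = include_self)
  micro <- cluster_compositions(comp, cells, K = config$n_microclusters,
                                seed = config$seeds$microclusters)
  comm <- merge_microclusters(micro, cells, strategy = "auto",
                              n_communities = n_communities)
  enr <- enrichment_scores(comm, cells)
  list(composition = comp, microclusters = micro, communities = comm,
       enrichment = enr, names = name_communities(enr), config = config)
}

#' Write pipeline outputs as delimited text with a run manifest
#'
#' Writes whichever standard outputs are supplied — per-cell community
#' assignments, per-sample enrichment matrices, a distance table, per-spot
#' scores — as headered CSV files with stable column order, plus a
#' `manifest.ini` recording the configuration and seeds so a run can be
#' reproduced exactly.
#'
#' @param out_dir output directory (created if needed).
#' @param config the `pipeline_config` of the run.
#' @param cells optional `cell_table` to accompany `communities`.
#' @param communities optional `community_assignment`.
#' @param enrichment optional `enrichment_matrix`.
#' @param distances optional `distance_table`.
#' @param scores optional named numeric vector of spot scores.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(out_dir, config, cells = NULL, communities = NULL,
                          enrichment = NULL, distances = NULL, scores = NULL) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = ",", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
  }
  if (!is.null(communities)) {
    stopifnot(!is.null(cells))
    emit(data.frame(sample_id = cells$sample_id, cell_id = cells$cell_id,
                    community = communities$community), "communities.csv")
  }
  if (!is.null(enrichment)) {
    rows <- list()
    for (s in names(enrichment)) {
      E <- enrichment[[s]]
      rows[[s]] <- data.frame(sample_id = s, community = rownames(E),
                              E, check.names = FALSE)
    }
    emit(do.call(rbind, rows), "enrichment.csv")
  }
  if (!is.null(distances)) emit(as.data.frame(distances), "distances.csv")
  if (!is.null(scores))
    emit(data.frame(spot_id = names(scores), score = as.numeric(scores)),
         "scores.csv")
  manifest <- file.path(out_dir, "manifest.ini")
  write_config(config, manifest)
  invisible(c(written, manifest))
}
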