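#' Cell-type vocabulary
#'
#' An ordered list of cell-type names, optionally flagging which names are
#' tumor states and which are myeloid populations.  The vocabulary fixes the
#' column order of every composition vector and enrichment matrix downstream,
#' so two runs over the same vocabulary are column-compatible.
#'
#' @param types character vector of unique, non-empty type names.
#' @param tumor_types,myeloid_types optional character subsets of `types`.
#' @return An object of class `type_vocabulary`.
#' @export
type_vocabulary <- function(types, tumor_types = character(), myeloid_types = character()) {
  types <- as.character(types)
  if (length(types) == 0L || anyNA(types) || any(!nzchar(types)))
    stop("type names must be non-empty and non-missing")
  if (anyDuplicated(types))
    stop("duplicate type names: ", paste(unique(types[duplicated(types)]), collapse = ", "))
  for (sub in list(tumor_types, myeloid_types)) {
    bad <- setdiff(sub, types)
    if (length(bad)) stop("subset flag names not in vocabulary: ", paste(bad, collapse = ", "))
  }
  structure(list(types = types,
                 tumor_types = as.character(tumor_types),
                 myeloid_types = as.character(myeloid_types)),
            class = "type_vocabulary")
}

#' Default 17-type vocabulary
#'
#' A vocabulary mirroring the granularity of CELESTA-style typing of a basal
#' cell carcinoma section: three tumor epithelial states (bulk tumor and the
#' BST and BIT transition states), a myeloid compartment (macrophages,
#' neutrophils, TREM1/TREM2 myeloid, dendritic cells), lymphocytes, stromal
#' and vascular types, and an explicit "Unknown" bucket for cells the typing
#' step could not assign.
#'
#' @return A `type_vocabulary` of 17 names.
#' @export
default_type_vocabulary <- function() {
  type_vocabulary(
    c("Tumor", "BST tumor", "BIT tumor",
      "Macrophage", "Neutrophil", "TREM1 myeloid", "TREM2 myeloid",
      "Dendritic cell", "T cell", "B cell", "NK cell", "Plasma cell",
      "Fibroblast", "Myofibroblast", "Endothelium", "Epithelium", "Unknown"),
    tumor_types = c("Tumor", "BST tumor", "BIT tumor"),
    myeloid_types = c("Macrophage", "Neutrophil", "TREM1 myeloid",
                      "TREM2 myeloid", "Dendritic cell")
  )
}

#' @export
print.type_vocabulary <- function(x, ...) {
  cat("type_vocabulary with", length(x$types), "types:\n ",
      paste(x$types, collapse = ", "), "\n")
  if (length(x$tumor_types))
    cat("  tumor types:  ", paste(x$tumor_types, collapse = ", "), "\n")
  if (length(x$myeloid_types))
    cat("  myeloid types:", paste(x$myeloid_types, collapse = ", "), "\n")
  invisible(x)
}
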