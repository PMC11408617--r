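#' Construct and validate a cell table
#'
#' A cell table is the pipeline's primary input: one row per segmented cell
#' with a sample identifier, a within-sample cell identifier, centroid
#' coordinates in pixels (image convention: origin top-left, y increases
#' downward), and a cell-type label drawn from a [type_vocabulary()].
#'
#' @param sample_id,cell_id character vectors; `(sample_id, cell_id)` pairs
#'   must be unique.
#' @param x_px,y_px finite, non-negative pixel coordinates.
#' @param cell_type character vector of type labels.
#' @param vocabulary a `type_vocabulary`, or `NULL` to build one from the
#'   labels observed (in order of first appearance).
#' @param strict if `TRUE`, labels absent from `vocabulary` are an error;
#'   otherwise they are remapped to `"Unknown"` (added to the vocabulary if
#'   needed) with a warning.
#' @return A `data.frame` of class `cell_table` with columns `sample_id`,
#'   `cell_id`, `x_px`, `y_px`, `cell_type`, and the vocabulary stored in
#'   `attr(, "vocabulary")`.
#' @export
cell_table <- function(sample_id, cell_id, x_px, y_px, cell_type,
                       vocabulary = NULL, strict = FALSE) {
  sample_id <- as.character(sample_id)
  cell_id <- as.character(cell_id)
  cell_type <- as.character(cell_type)
  x_px <- as.numeric(x_px)
  y_px <- as.numeric(y_px)
  n <- length(sample_id)
  if (length(cell_id) != n || length(x_px) != n || length(y_px) != n ||
      length(cell_type) != n)
    stop("all cell table columns must have equal length")
  if (anyNA(sample_id) || anyNA(cell_id))
    stop("missing sample or cell identifiers")
  key <- paste(sample_id, cell_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (sample_id, cell_id) key: ", gsub("\r", "/", d, fixed = TRUE))
  }
  if (anyNA(x_px) || anyNA(y_px) || any(!is.finite(x_px)) || any(!is.finite(y_px)))
    stop("coordinates must be finite and non-missing")
  if (any(x_px < 0) || any(y_px < 0))
    stop("pixel coordinates must be non-negative")
  if (anyNA(cell_type) || any(!nzchar(cell_type)))
    stop("missing cell-type labels (use an explicit \"Unknown\" label instead)")

  if (is.null(vocabulary)) {
    vocabulary <- type_vocabulary(unique(cell_type))
  } else {
    stopifnot(inherits(vocabulary, "type_vocabulary"))
    unknown <- setdiff(unique(cell_type), vocabulary$types)
    if (length(unknown)) {
      if (strict)
        stop("unrecognized cell-type labels: ", paste(unknown, collapse = ", "))
      warning("remapping unrecognized labels to \"Unknown\": ",
              paste(unknown, collapse = ", "))
      cell_type[cell_type %in% unknown] <- "Unknown"
      if (!"Unknown" %in% vocabulary$types)
        vocabulary <- type_vocabulary(c(vocabulary$types, "Unknown"),
                                      vocabulary$tumor_types, vocabulary$myeloid_types)
    }
  }
  out <- data.frame(sample_id = sample_id, cell_id = cell_id,
                    x_px = x_px, y_px = y_px, cell_type = cell_type,
                    stringsAsFactors = FALSE)
  attr(out, "vocabulary") <- vocabulary
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Vocabulary attached to a cell table
#' @param cells a `cell_table`.
#' @return The `type_vocabulary` the table was validated against.
#' @export
cell_vocabulary <- function(cells) {
  stopifnot(inherits(cells, "cell_table"))
  attr(cells, "vocabulary")
}

#' @export
print.cell_table <- function(x, ...) {
  cat("cell_table:", nrow(x), "cells,",
      length(unique(x$sample_id)), "sample(s),",
      length(cell_vocabulary(x)$types), "types in vocabulary\n")
  print(head(as.data.frame(x), 6L))
  invisible(x)
}

# default header names; CODEX processors disagree, so read_cell_table lets
# callers override each one
.cell_table_columns <- c(sample_id = "sample_id", cell_id = "cell_id",
                         x = "x", y = "y", cell_type = "cell_type")

#' Read a cell table from delimited text
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param vocabulary optional `type_vocabulary` to validate labels against.
#' @param columns named character vector mapping the logical roles
#'   `sample_id`, `cell_id`, `x`, `y`, `cell_type` to header names in the
#'   file; defaults to those names themselves.
#' @param sep field separator; `","` for CSV (default), `"\t"` for TSV.
#' @param strict passed to [cell_table()]: whether unknown labels are fatal.
#' @return A validated `cell_table`.
#' @export
read_cell_table <- function(path, vocabulary = NULL,
                            columns = .cell_table_columns,
                            sep = ",", strict = FALSE) {
  columns <- utils::modifyList(as.list(.cell_table_columns), as.list(columns))
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  need <- unlist(columns, use.names = FALSE)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop(path, ": missing required column(s): ", paste(missing_cols, collapse = ", "))
  xs <- suppressWarnings(as.numeric(raw[[columns$x]]))
  ys <- suppressWarnings(as.numeric(raw[[columns$y]]))
  bad <- which(is.na(xs) | is.na(ys))
  if (length(bad))
    stop(path, ": non-numeric coordinate on data line ", bad[1L],
         " (x=", raw[[columns$x]][bad[1L]], ", y=", raw[[columns$y]][bad[1L]], ")")
  cell_table(raw[[columns$sample_id]], raw[[columns$cell_id]], xs, ys,
             raw[[columns$cell_type]], vocabulary = vocabulary, strict = strict)
}

#' Write a cell table as delimited text
#'
#' Writes the five standard columns with their default header names.  A table
#' written by this function re-reads to an identical object with
#' [read_cell_table()].
#'
#' @param cells a `cell_table`.
#' @param path output file path.
#' @param sep field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path, sep = ",") {
  stopifnot(inherits(cells, "cell_table"))
  out <- as.data.frame(cells)
  names(out) <- c("sample_id", "cell_id", "x", "y", "cell_type")
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
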