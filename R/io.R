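#' Read a delimited expression (or feature) matrix
#'
#' Reads a genes x samples matrix from delimited text: a header row of
#' sample ids, first column of gene ids, numeric cells.  Lines starting
#' with `#` (metadata written by the package's writers) are skipped.
#' Because square correlation-feature matrices are written in the same
#' layout (sample ids in both the header and first column), this reader
#' loads those too.
#'
#' @param path file to read.
#' @param sep field delimiter (default tab; use `","` for CSV).
#' @param missing policy for missing or non-numeric cells: `"error"`
#'   (default) or `"drop"` (remove affected gene rows with a warning).
#'
#' @return numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
read_expression <- function(path, sep = "\t", missing = c("error", "drop")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("expected a gene-id column plus at least 2 sample columns in ",
         path, call. = FALSE)
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  X <- suppressWarnings(
    vapply(df[-1L], function(col) as.numeric(as.character(col)),
           numeric(nrow(df))))
  X <- matrix(X, nrow = nrow(df), ncol = length(sample_ids),
              dimnames = list(gene_ids, sample_ids))
  if (anyNA(X)) {
    bad <- which(apply(X, 1L, anyNA))
    if (missing == "error")
      stop("missing or non-numeric values in ", length(bad), " gene row(s) ",
           "of ", path, " (first: ", gene_ids[bad[1L]],
           "); use missing = \"drop\" to remove them", call. = FALSE)
    warning("dropping ", length(bad), " gene row(s) with missing values",
            call. = FALSE)
    X <- X[-bad, , drop = FALSE]
  }
  if (nrow(X) < 1L) stop("no gene rows left in ", path, call. = FALSE)
  X
}

#' Read a two-column sample-to-label file
#'
#' Reads class or batch labels: first column sample id, second column
#' label.  Lines starting with `#` are skipped.
#'
#' @param path file to read.
#' @param sep field delimiter (default tab).
#' @param header does the file carry a header row (default `TRUE`)?
#'
#' @return character vector of labels named by sample id.
#' @export
read_labels <- function(path, sep = "\t", header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = header, sep = sep, quote = "",
                      comment.char = "#", check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) < 1L) stop("no label rows in ", path, call. = FALSE)
  if (ncol(df) < 2L)
    stop("expected two columns (sample id, label) in ", path, call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample ids in ", path, call. = FALSE)
  stats::setNames(as.character(df[[2L]]), ids)
}

#' Write a matrix as delimited text
#'
#' Writes a genes x samples (or samples x samples feature) matrix with the
#' layout [read_expression()] reads back: optional `# `-prefixed metadata
#' lines, a header row, an id column, and values formatted with 10
#' significant digits.  Re-running the identical command reproduces a
#' byte-identical file; numeric round-trips are exact to the printed
#' precision, so comparisons should be numeric, not textual.
#'
#' @param X numeric matrix with dimnames.
#' @param path output file.
#' @param sep field delimiter (default tab).
#' @param id_col name of the id column in the header (default `"id"`).
#' @param digits significant digits to print (default 10).
#' @param meta character vector of metadata lines (tool version, command
#'   line, seed, ...) written as `# `-prefixed comments.
#' @return `path`, invisibly.
#' @export
write_expression <- function(X, path, sep = "\t", id_col = "id",
                             digits = 10L, meta = character()) {
  X <- as.matrix(X)
  ids <- rownames(X) %||% paste0("row", seq_len(nrow(X)))
  cols <- colnames(X) %||% paste0("col", seq_len(ncol(X)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  writeLines(paste(c(id_col, cols), collapse = sep), con)
  body <- apply(X, 1L, function(row)
    paste(formatC(row, digits = digits, format = "g"), collapse = sep))
  writeLines(paste(ids, body, sep = sep), con)
  invisible(path)
}

#' @rdname write_expression
#' @param C a [corr_features][new_corr_features] matrix; written with sample
#'   ids in both header and id column, and its order recorded in the
#'   metadata.
#' @export
write_features <- function(C, path, sep = "\t", digits = 10L,
                           meta = character()) {
  ord <- feature_order(C)
  if (!is.na(ord)) meta <- c(meta, paste0("order: ", ord))
  write_expression(unclass_matrix(C), path, sep = sep, id_col = "sample_id",
                   digits = digits, meta = meta)
}

#' Write a two-column sample-to-label file
#'
#' @param labels vector of labels named by sample id.
#' @param path output file.
#' @param sep field delimiter.
#' @param col_names header column names.
#' @param meta metadata comment lines, as in [write_expression()].
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, sep = "\t",
                         col_names = c("sample_id", "label"),
                         meta = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  writeLines(paste(col_names, collapse = sep), con)
  writeLines(paste(names(labels), as.character(labels), sep = sep), con)
  invisible(path)
}
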