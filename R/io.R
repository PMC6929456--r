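#' Read an expression matrix from disk
#'
#' Reads a cells-by-genes expression matrix from a dense CSV/TSV file or a
#' Matrix Market (`.mtx`) triplet file with plain-text row/column name
#' sidecars. On-disk matrices in single-cell work conventionally store genes
#' as rows, so the default `orientation` is `"genes_by_cells"` and the matrix
#' is transposed on read; the returned matrix is always cells x genes with
#' cell identifiers as row names and gene identifiers as column names.
#'
#' For dense formats the first column holds row identifiers and the header
#' row holds column identifiers. For `format = "mtx"`, `row_names` and
#' `col_names` name one-identifier-per-line sidecar files; they default to
#' `<stem>_rows.txt` and `<stem>_cols.txt` next to the matrix file.
#'
#' @param path Path to the matrix file.
#' @param format One of `"auto"` (from the file extension), `"csv"`, `"tsv"`,
#'   `"mtx"`.
#' @param orientation How the on-disk matrix is laid out: `"genes_by_cells"`
#'   (default) or `"cells_by_genes"`.
#' @param unit Free-text unit tag attached to the matrix (e.g. `"FPKM"`,
#'   `"counts"`). [log_transform()] refuses matrices already tagged as
#'   log-transformed.
#' @param row_names,col_names Sidecar identifier files, MTX format only.
#' @return A numeric cells x genes matrix with a `"unit"` attribute.
#' @seealso [write_expression()], [read_annotation()]
#' @export
read_expression <- function(path,
                            format = c("auto", "csv", "tsv", "mtx"),
                            orientation = c("genes_by_cells", "cells_by_genes"),
                            unit = "FPKM",
                            row_names = NULL, col_names = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop("expression file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
      stop("cannot infer format from extension of '", path,
           "'; pass format=", call. = FALSE))
  }
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- read.csv(path, sep = sep, check.names = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) {
      stop("duplicated ", if (orientation == "genes_by_cells") "gene"
           else "cell", " identifiers in ", path, call. = FALSE)
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
  } else {
    stem <- sub("\\.mtx$", "", path)
    if (is.null(row_names)) row_names <- paste0(stem, "_rows.txt")
    if (is.null(col_names)) col_names <- paste0(stem, "_cols.txt")
    for (f in c(row_names, col_names)) {
      if (!file.exists(f)) {
        stop("MTX sidecar file not found: ", f, call. = FALSE)
      }
    }
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(row_names)
    cn <- readLines(col_names)
    if (length(rn) != nrow(m)) {
      stop("row-name sidecar has ", length(rn), " identifiers but the matrix ",
           "has ", nrow(m), " rows", call. = FALSE)
    }
    if (length(cn) != ncol(m)) {
      stop("column-name sidecar has ", length(cn), " identifiers but the ",
           "matrix has ", ncol(m), " columns", call. = FALSE)
    }
    dimnames(m) <- list(rn, cn)
  }
  if (orientation == "genes_by_cells") m <- t(m)
  validate_expression(m, unit = unit)
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]: writes the matrix in the requested
#' on-disk orientation with identifiers, so that reading it back recovers
#' the identical cells x genes matrix.
#'
#' @param x Cells x genes matrix with identifiers.
#' @param path Output file; extension selects CSV or TSV.
#' @param orientation On-disk layout, as in [read_expression()].
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path,
                             orientation = c("genes_by_cells", "cells_by_genes")) {
  orientation <- match.arg(orientation)
  m <- if (orientation == "genes_by_cells") t(x) else x
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- ""
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_expression <- function(m, unit = attr(m, "unit")) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix must carry cell (row) and gene (column) ",
         "identifiers", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicated cell identifiers in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicated gene identifiers in expression matrix", call. = FALSE)
  }
  if (any(!is.finite(m))) {
    stop("expression matrix contains non-finite values", call. = FALSE)
  }
  raw_unit <- is.null(unit) || !grepl("log", unit, ignore.case = TRUE)
  if (raw_unit && any(m < 0)) {
    stop("expression matrix in raw units contains negative values",
         call. = FALSE)
  }
  attr(m, "unit") <- if (is.null(unit)) "FPKM" else unit
  m
}

#' Read a per-cell annotation file
#'
#' Reads a two-column file (`cell_id,label`) and aligns it to the rows of an
#' expression matrix. The cell type set is taken as the distinct labels in
#' first-appearance order (in the order of the expression matrix), so that
#' downstream class ordering never depends on locale collation.
#'
#' @param path Two-column CSV with a header row.
#' @param expr Cells x genes matrix the annotation must cover.
#' @param strict If `TRUE` (default) cell ids in the file that are absent
#'   from `expr` are an error; if `FALSE` they are dropped with a warning.
#' @return A factor of length `nrow(expr)`, named by cell id, in `expr` row
#'   order.
#' @export
read_annotation <- function(path, expr, strict = TRUE) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) {
    stop("annotation file must have two columns: cell_id, label",
         call. = FALSE)
  }
  ids <- as.character(df[[1]])
  labs <- as.character(df[[2]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicated cell ids in annotation file: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(ids, rownames(expr))
  if (length(unknown)) {
    msg <- paste0(length(unknown), " annotated cell id(s) absent from the ",
                  "expression matrix: ",
                  paste(utils::head(unknown, 5), collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
    keep <- ids %in% rownames(expr)
    ids <- ids[keep]; labs <- labs[keep]
  }
  missing <- setdiff(rownames(expr), ids)
  if (length(missing)) {
    stop(length(missing), " cell(s) in the expression matrix have no ",
         "annotation: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  labs <- labs[match(rownames(expr), ids)]
  stats::setNames(factor(labs, levels = unique(labs)), rownames(expr))
}

#' Write a label-correction result table
#'
#' Writes one row per cell: `cell_id`, `original_label`, `predicted_label`,
#' `changed`, `max_probability`, followed by one ensemble probability column
#' per cell type (`prob_<type>`), in the input cell order.
#'
#' @param fit A [relabel()] fit.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_result <- function(fit, path) {
  df <- as.data.frame(fit)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
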