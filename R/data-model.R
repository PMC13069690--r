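#' Read a cell coordinate table
#'
#' Reads a delimited table of cell centroids exported from a spatial
#' transcriptomics platform (Xenium, MERFISH, Visium HD exports all reduce to
#' this form). The header must contain the columns \code{x}, \code{y},
#' \code{cell} and \code{cluster} (case-insensitive); any extra columns are
#' carried through untouched so platform exports need no pre-editing.
#'
#' @param path Path to a CSV or TSV file with a header row.
#' @param dialect Either \code{"auto"} (decide from the file extension,
#'   defaulting to TSV), \code{"csv"} or \code{"tsv"}.
#' @return A validated \code{data.frame} with canonical columns \code{cell},
#'   \code{x}, \code{y}, \code{cluster} first (input row order preserved),
#'   followed by any extra columns.
#' @export
read_cell_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("coordinate file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  names_lc <- tolower(names(df))
  for (col in c("x", "y", "cell", "cluster")) {
    if (!col %in% names_lc) {
      stop("coordinate file is missing required column '", col, "'")
    }
  }
  # canonicalise the four required names, keep extras as-is
  names(df)[match(c("x", "y", "cell", "cluster"), names_lc)] <-
    c("x", "y", "cell", "cluster")
  for (col in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    bad <- c(bad, which(is.na(df[[col]]) | !nzchar(df[[col]])))
    if (length(bad) > 0) {
      stop("non-numeric '", col, "' coordinate at row ", min(bad))
    }
    df[[col]] <- v
  }
  extra <- setdiff(names(df), c("cell", "x", "y", "cluster"))
  df <- df[, c("cell", "x", "y", "cluster", extra), drop = FALSE]
  validate_cell_table(df)
  df
}

#' Validate a cell coordinate table
#'
#' Checks the invariants every downstream stage relies on: unique non-empty
#' cell ids, finite coordinates, at least one cell and one cluster label.
#' Cluster labels are treated as opaque categories; numeric and string labels
#' are both accepted.
#'
#' @param cells A data.frame with columns \code{cell}, \code{x}, \code{y},
#'   \code{cluster}.
#' @return The input, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_cell_table <- function(cells) {
  if (!is.data.frame(cells)) stop("cell table must be a data.frame")
  miss <- setdiff(c("cell", "x", "y", "cluster"), names(cells))
  if (length(miss) > 0) {
    stop("cell table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(cells) < 1) stop("cell table has no rows")
  ids <- as.character(cells$cell)
  if (any(is.na(ids) | !nzchar(ids))) stop("empty or missing cell id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stop("duplicate cell id: '", dup[1], "'")
  if (!is.numeric(cells$x) || !is.numeric(cells$y)) {
    stop("x and y must be numeric")
  }
  if (!all(is.finite(cells$x)) || !all(is.finite(cells$y))) {
    stop("non-finite coordinate value")
  }
  if (all(is.na(cells$cluster))) stop("no cluster labels present")
  invisible(cells)
}

#' Write a cell coordinate table as TSV
#'
#' @param cells A cell table (see \code{\link{validate_cell_table}}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.table(cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a gene-by-cell expression matrix
#'
#' Supports MatrixMarket triplet format with sidecar gene/cell name files, or
#' dense delimited text with gene ids in the first column and cell ids in the
#' header. Expression is assumed already normalised and log-transformed
#' upstream; values must be finite and non-negative. No normalisation is
#' performed here.
#'
#' @param path Matrix file (MTX) or dense table.
#' @param format \code{"auto"} (from extension), \code{"mtx"} or
#'   \code{"dense"}.
#' @param genes,cells For MTX input: paths to plain-text files with one gene
#'   (row) or cell (column) name per line.
#' @param sep Field separator for dense input (default tab; comma files are
#'   detected from a \code{.csv} extension under \code{format = "auto"}).
#' @return A \code{dgCMatrix} (MTX input) or base matrix (dense input) with
#'   genes as rows and cells as columns, dimnames set.
#' @export
read_expression <- function(path, format = c("auto", "mtx", "dense"),
                            genes = NULL, cells = NULL, sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (format == "auto") {
    if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
      format <- "mtx"
    } else {
      format <- "dense"
      if (grepl("\\.csv$", path, ignore.case = TRUE)) sep <- ","
    }
  }
  if (format == "mtx") {
    if (is.null(genes) || is.null(cells)) {
      stop("MTX input requires 'genes' and 'cells' name files")
    }
    m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    gn <- readLines(genes)
    cn <- readLines(cells)
    if (length(gn) != nrow(m)) {
      stop("gene name count mismatch: matrix has ", nrow(m),
           " rows but ", length(gn), " names supplied")
    }
    if (length(cn) != ncol(m)) {
      stop("cell name count mismatch: matrix has ", ncol(m),
           " columns but ", length(cn), " names supplied")
    }
    dimnames(m) <- list(gn, cn)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, comment.char = "")
    if (nrow(df) == 0 || ncol(df) == 0) stop("empty expression matrix")
    m <- as.matrix(df)
    storage.mode(m) <- "double"
  }
  validate_expression(m)
  m
}

#' Validate an expression matrix
#'
#' @param expr Matrix (dense or \code{dgCMatrix}) with gene rows and cell
#'   columns, dimnames set.
#' @return The input, invisibly.
#' @export
validate_expression <- function(expr) {
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix must carry gene rownames and cell colnames")
  }
  if (nrow(expr) == 0 || ncol(expr) == 0) stop("empty expression matrix")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(expr))) stop("duplicate cell ids")
  v <- if (methods::is(expr, "sparseMatrix")) expr@x else expr
  if (length(v) > 0 && (!all(is.finite(v)) || any(v < 0))) {
    stop("expression values must be finite and non-negative (log scale)")
  }
  invisible(expr)
}

#' Write an expression matrix
#'
#' Dense output round-trips through \code{\link{read_expression}} at full
#' precision.
#'
#' @param expr Gene-by-cell matrix with dimnames.
#' @param path Output path: \code{.mtx} writes MatrixMarket triplets with
#'   sidecar \code{<path>.genes.txt} / \code{<path>.cells.txt}; anything else
#'   writes a dense TSV.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(expr, path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(methods::as(methods::as(expr, "dMatrix"), "CsparseMatrix"),
                    path)
    writeLines(rownames(expr), paste0(path, ".genes.txt"))
    writeLines(colnames(expr), paste0(path, ".cells.txt"))
  } else {
    m <- as.matrix(expr)
    # %.17g round-trips doubles exactly through the reader
    chm <- matrix(sprintf("%.17g", m), nrow(m))
    df <- data.frame(gene = rownames(m), chm, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c("gene", colnames(m))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Align a coordinate table with an expression matrix
#'
#' Restricts both inputs to the cells present in each, in a single shared
#' order, and reports how many cells were dropped from either side. Aligning
#' an already aligned pair is a no-op.
#'
#' @param cells A validated cell table.
#' @param expr A gene-by-cell expression matrix with cell colnames.
#' @return A list with elements \code{cells}, \code{expr},
#'   \code{dropped_cells} (count dropped from the coordinate side) and
#'   \code{dropped_expr} (count dropped from the expression side).
#' @export
align_dataset <- function(cells, expr) {
  validate_cell_table(cells)
  ids_c <- as.character(cells$cell)
  ids_e <- colnames(expr)
  common <- ids_c[ids_c %in% ids_e]
  if (length(common) == 0) {
    stop("no cell ids shared between coordinates and expression")
  }
  list(cells = cells[match(common, ids_c), , drop = FALSE],
       expr = expr[, match(common, ids_e), drop = FALSE],
       dropped_cells = length(ids_c) - length(common),
       dropped_expr = length(ids_e) - length(common))
}
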