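#' Read an expression matrix from disk
#'
#' Reads either a dense delimited file (TSV or CSV, delimiter sniffed) with a
#' header line and row identifiers in the first column, or a 10x-style
#' Matrix Market triplet directory containing a `.mtx` file plus
#' newline-delimited barcode and feature sidecar files. The returned matrix
#' is always oriented cells x genes.
#'
#' For triplet directories the axis carrying the barcodes is detected from
#' the sidecar lengths (10x convention stores genes as rows), so the
#' `orientation` argument only matters for dense files.
#'
#' @param path Path to a delimited file, or to a directory holding
#'   `matrix.mtx`, `barcodes.tsv` and `features.tsv` (or `genes.tsv`).
#' @param orientation Either `"cells_as_rows"` (default) or
#'   `"genes_as_rows"`; how the *input* dense file is laid out.
#' @return A numeric matrix (cells x genes) with unique cell identifiers as
#'   row names and gene identifiers as column names. Matrices with more than
#'   50% zeros read from Matrix Market input are returned as sparse
#'   `dgCMatrix`.
#' @export
read_expression <- function(path, orientation = c("cells_as_rows", "genes_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop("input not found: ", path)
  }
  if (dir.exists(path)) {
    X <- .read_mtx_dir(path)
  } else {
    X <- .read_dense(path)
    if (orientation == "genes_as_rows") X <- t(X)
  }
  .validate_ids(rownames(X), "cell")
  .validate_ids(colnames(X), "gene")
  X
}

.read_dense <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  ids <- as.character(dt[[1L]])
  vals <- dt[, -1L, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    col <- which(bad)[1L]
    suppressWarnings(num <- as.numeric(vals[[col]]))
    row <- which(is.na(num) & !is.na(vals[[col]]))[1L]
    stop(sprintf("non-numeric value at row %s, column '%s' of %s",
                 ifelse(is.na(row), "?", row), names(vals)[col], path))
  }
  X <- as.matrix(vals)
  rownames(X) <- ids
  X
}

.read_mtx_dir <- function(path) {
  mtx <- .find_one(path, c("matrix.mtx", "*.mtx"))
  bar <- .find_one(path, c("barcodes.tsv", "barcodes.txt"))
  fea <- .find_one(path, c("features.tsv", "genes.tsv", "features.txt", "genes.txt"))
  M <- Matrix::readMM(mtx)
  barcodes <- readLines(bar)
  features <- .first_column(fea)
  if (nrow(M) == length(features) && ncol(M) == length(barcodes)) {
    M <- Matrix::t(M)           # 10x layout: genes x cells on disk
  } else if (!(nrow(M) == length(barcodes) && ncol(M) == length(features))) {
    stop(sprintf("matrix is %d x %d but there are %d barcodes and %d features",
                 nrow(M), ncol(M), length(barcodes), length(features)))
  }
  dimnames(M) <- list(barcodes, features)
  dens <- Matrix::nnzero(M) / prod(dim(M))
  if (dens > .SPARSE_THRESHOLD) as.matrix(M) else methods::as(M, "CsparseMatrix")
}

.find_one <- function(dir, patterns) {
  for (p in patterns) {
    hit <- Sys.glob(file.path(dir, p))
    if (length(hit) >= 1L) return(hit[1L])
  }
  stop("no file matching ", paste(patterns, collapse = "/"), " in ", dir)
}

.first_column <- function(path) {
  lines <- readLines(path)
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

.validate_ids <- function(ids, what) {
  if (is.null(ids)) stop("missing ", what, " identifiers")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate ", what, " identifiers: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  invisible(ids)
}

#' Write an expression matrix as a dense delimited file
#'
#' Companion to [read_expression()]; cells as rows, first column holds cell
#' identifiers.
#'
#' @param X cells x genes matrix with dimnames.
#' @param path Output file; `.csv` extension selects comma, otherwise tab.
#' @return `path`, invisibly.
#' @export
write_expression <- function(X, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  X <- as.matrix(X)
  df <- data.frame(cell_id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write cluster labels as a two-column TSV
#'
#' @param labels Integer label vector, or an object with a `$labels` field
#'   (e.g. the result of [spectral_cluster()]).
#' @param cell_ids Character vector of the same length, in input cell order.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, cell_ids, path) {
  if (is.list(labels) && !is.null(labels$labels)) labels <- labels$labels
  if (length(labels) == 0L) stop("no labels to write")
  if (length(labels) != length(cell_ids)) {
    stop(sprintf("%d labels but %d cell ids", length(labels), length(cell_ids)))
  }
  utils::write.table(
    data.frame(cell_id = cell_ids, cluster = as.integer(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cluster labels written by [write_labels()]
#'
#' @param path Two-column TSV with a header.
#' @return Named integer vector of labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  out <- as.integer(df[[2L]])
  names(out) <- as.character(df[[1L]])
  out
}

#' Write a square cell-cell graph matrix
#'
#' Used to export the affinity `W` or the diffused similarity `S` for
#' external visualization. Dense TSV keeps 15 significant digits so a
#' read-back round trip is lossless to print precision; asymmetric matrices
#' are written as-is.
#'
#' @param M Square numeric matrix (base or `Matrix`).
#' @param cell_ids Identifiers, length `nrow(M)`.
#' @param path Output path (`.mtx` sidecar ids get written to
#'   `<path>.ids.tsv` for `format = "mtx"`).
#' @param format `"dense_tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(M, cell_ids = rownames(M), path,
                        format = c("dense_tsv", "mtx")) {
  format <- match.arg(format)
  if (nrow(M) != ncol(M)) stop("graph matrix must be square")
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(M)))
  if (length(cell_ids) != nrow(M)) stop("cell_ids length must equal nrow(M)")
  if (format == "dense_tsv") {
    Md <- as.matrix(M)
    df <- data.frame(cell_id = cell_ids,
                     format(Md, digits = 15, scientific = TRUE, trim = TRUE),
                     check.names = FALSE)
    colnames(df) <- c("cell_id", cell_ids)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(methods::as(M, "CsparseMatrix"), "generalMatrix"), path)
    writeLines(cell_ids, paste0(path, ".ids.tsv"))
  }
  invisible(path)
}

#' Read a graph matrix written by [write_graph()]
#'
#' @param path `.mtx` file or dense TSV.
#' @return Square numeric matrix with cell identifiers as dimnames (dense
#'   for TSV input, sparse for MTX).
#' @export
read_graph <- function(path) {
  if (grepl("\\.mtx$", path)) {
    M <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    ids_path <- paste0(path, ".ids.tsv")
    if (file.exists(ids_path)) {
      ids <- readLines(ids_path)
      dimnames(M) <- list(ids, ids)
    }
    return(M)
  }
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1L, drop = FALSE])
  rownames(M) <- as.character(df[[1L]])
  M
}
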