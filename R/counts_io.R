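#' Read a 10x-style gene x cell UMI count matrix
#'
#' Reads the standard 10x Genomics triple (MatrixMarket `matrix.mtx`,
#' `features.tsv`, `barcodes.tsv`, each optionally gzip-compressed) into a
#' sparse gene x cell integer count matrix. Gene symbols are taken from the
#' second column of the features file when present (10x puts Ensembl ids in
#' column 1 and symbols in column 2), otherwise from the first.
#'
#' @param path Directory containing `matrix.mtx(.gz)`, `features.tsv(.gz)` (or
#'   `genes.tsv(.gz)`) and `barcodes.tsv(.gz)`; alternatively a character
#'   vector of length 3 giving the matrix, features and barcodes paths in that
#'   order.
#' @return A [`Matrix::dgCMatrix`][Matrix::dgCMatrix-class] with genes as rows
#'   (rownames = symbols) and cells as columns (colnames = barcodes).
#' @details The on-disk orientation is normalized: if the stored matrix is
#'   cells x genes it is transposed so that rows always index genes. Duplicate
#'   barcodes are an error; duplicate gene symbols are made unique with
#'   [make.unique()] and a warning. Non-integer or negative values are errors.
#' @seealso [write_counts_10x()], [compute_cell_qc()]
#' @export
read_counts_10x <- function(path) {
  if (length(path) == 1 && dir.exists(path)) {
    files <- c(
      .find_10x_file(path, c("matrix.mtx", "matrix.mtx.gz")),
      .find_10x_file(path, c("features.tsv", "features.tsv.gz",
                             "genes.tsv", "genes.tsv.gz")),
      .find_10x_file(path, c("barcodes.tsv", "barcodes.tsv.gz"))
    )
  } else if (length(path) == 3) {
    files <- path
    missing <- files[!file.exists(files)]
    if (length(missing)) {
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
    }
  } else {
    stop("'path' must be a 10x matrix directory or the three file paths ",
         "(matrix, features, barcodes)")
  }

  m <- Matrix::readMM(.maybe_gz(files[1]))
  feat <- utils::read.delim(.maybe_gz(files[2]), header = FALSE,
                            stringsAsFactors = FALSE)
  bc <- utils::read.delim(.maybe_gz(files[3]), header = FALSE,
                          stringsAsFactors = FALSE)[[1]]
  genes <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]

  if (anyDuplicated(bc)) {
    stop("duplicate cell barcodes in ", files[3], ": ",
         paste(unique(bc[duplicated(bc)]), collapse = ", "))
  }
  if (anyDuplicated(genes)) {
    warning("duplicate gene symbols made unique with make.unique()")
    genes <- make.unique(genes)
  }

  if (nrow(m) == length(genes) && ncol(m) == length(bc)) {
    # genes x cells as stored
  } else if (nrow(m) == length(bc) && ncol(m) == length(genes)) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf(
      "matrix dimensions (%d x %d) match neither %d features x %d barcodes nor its transpose",
      nrow(m), ncol(m), length(genes), length(bc)))
  }

  m <- methods::as(m, "CsparseMatrix")
  v <- m@x
  if (any(v < 0) || any(v != round(v))) {
    stop("count matrix must contain non-negative integers")
  }
  dimnames(m) <- list(genes, bc)
  m
}

#' Write a count matrix as a 10x-style triple
#'
#' Inverse of [read_counts_10x()]: writes `matrix.mtx`, `features.tsv` and
#' `barcodes.tsv` into `dir` (created if needed). The features file carries the
#' gene symbol in both columns, which `read_counts_10x()` accepts.
#'
#' @param counts gene x cell matrix with dimnames (sparse or dense).
#' @param dir output directory.
#' @param gzip compress the three files with gzip.
#' @return Invisibly, the three file paths written.
#' @export
write_counts_10x <- function(counts, dir, gzip = FALSE) {
  counts <- as_count_matrix(counts)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (gzip) ".gz" else ""
  paths <- file.path(dir, paste0(c("matrix.mtx", "features.tsv", "barcodes.tsv"), ext))

  if (gzip) {
    tmp <- tempfile(fileext = ".mtx")
    Matrix::writeMM(counts, tmp)
    con <- gzfile(paths[1], "wb")
    writeLines(readLines(tmp), con)
    close(con)
    unlink(tmp)
  } else {
    Matrix::writeMM(counts, paths[1])
  }
  .write_tsv_plain(data.frame(rownames(counts), rownames(counts)), paths[2], gzip)
  .write_tsv_plain(data.frame(colnames(counts)), paths[3], gzip)
  invisible(paths)
}

#' Coerce to a validated sparse count matrix
#'
#' @param x gene x cell matrix-like object with gene symbols as rownames and
#'   barcodes as colnames.
#' @return A `dgCMatrix` satisfying the count-matrix invariants (unique
#'   dimnames, non-negative integral entries).
#' @export
as_count_matrix <- function(x) {
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("count matrix needs gene symbols as rownames and barcodes as colnames")
  }
  m <- if (methods::is(x, "sparseMatrix")) {
    methods::as(methods::as(x, "generalMatrix"), "CsparseMatrix")
  } else {
    methods::as(Matrix::Matrix(as.matrix(x) * 1.0, sparse = TRUE),
                "CsparseMatrix")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene symbols")
  if (anyDuplicated(colnames(m))) stop("duplicate cell barcodes")
  if (length(m@x) && (any(m@x < 0) || any(m@x != round(m@x)))) {
    stop("count matrix must contain non-negative integers")
  }
  m
}

.find_10x_file <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop("none of ", paste(candidates, collapse = "/"), " found in ", dir)
}

.maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

.write_tsv_plain <- function(df, path, gzip = FALSE) {
  con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}
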