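#' Quality-control thresholds for TIL single-cell expression data
#'
#' Container for the per-cell gates applied before any downstream analysis:
#' detected-gene window, mitochondrial UMI fraction, and mean CD3 UMI count
#' (a T cell identity gate). Defaults are the screening protocol's values:
#' cells are kept when the detected gene number lies in \[800, 10000\]
#' (inclusive), the mitochondrial fraction is strictly below 0.2, and the
#' mean raw UMI count of CD3D/CD3E/CD3G is strictly above 0.
#'
#' @param min_genes,max_genes inclusive bounds on the number of genes with at
#'   least one UMI.
#' @param max_pct_mito exclusive upper bound on the mitochondrial UMI
#'   fraction (in \[0, 1\]).
#' @param min_cd3_mean exclusive lower bound on the mean raw UMI count over
#'   `cd3_genes`.
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes,
#'   matched case-insensitively.
#' @param cd3_genes gene symbols whose mean raw UMI defines the CD3 gate. The
#'   mean always divides by `length(cd3_genes)`; symbols absent from the
#'   matrix contribute 0 (with a warning), and it is an error if none are
#'   present.
#' @param scale_factor library-size scale factor used by [log_normalize()].
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 800, max_genes = 10000,
                          max_pct_mito = 0.2, min_cd3_mean = 0,
                          mito_prefix = "MT-",
                          cd3_genes = c("CD3D", "CD3E", "CD3G"),
                          scale_factor = 10000) {
  stopifnot(min_genes <= max_genes,
            max_pct_mito > 0, max_pct_mito <= 1,
            length(cd3_genes) >= 1,
            scale_factor > 0)
  structure(
    list(min_genes = min_genes, max_genes = max_genes,
         max_pct_mito = max_pct_mito, min_cd3_mean = min_cd3_mean,
         mito_prefix = mito_prefix, cd3_genes = cd3_genes,
         scale_factor = scale_factor),
    class = "qc_thresholds")
}

#' Per-cell quality-control metrics
#'
#' Computes, on RAW counts, the number of detected genes, total UMIs,
#' mitochondrial UMI fraction and mean CD3 UMI count for every cell.
#'
#' @param counts gene x cell count matrix (see [as_count_matrix()]).
#' @param thresholds a [qc_thresholds()] object (supplies the mitochondrial
#'   prefix and CD3 gene set).
#' @return A data frame with one row per barcode, in matrix column order:
#'   `barcode`, `n_genes`, `total_umi`, `pct_mito`, `cd3_mean`. A cell with
#'   zero total UMIs has `pct_mito = 0` (0/0 is defined as 0).
#' @export
compute_cell_qc <- function(counts, thresholds = qc_thresholds()) {
  counts <- as_count_matrix(counts)
  if (nrow(counts) == 0 || ncol(counts) == 0) {
    stop("count matrix is empty")
  }
  genes <- rownames(counts)

  cd3_present <- intersect(thresholds$cd3_genes, genes)
  if (length(cd3_present) == 0) {
    stop("none of the CD3 genes (",
         paste(thresholds$cd3_genes, collapse = ", "),
         ") are present in the count matrix")
  }
  cd3_missing <- setdiff(thresholds$cd3_genes, genes)
  if (length(cd3_missing)) {
    warning("CD3 gene(s) absent from the matrix and counted as 0: ",
            paste(cd3_missing, collapse = ", "))
  }

  mito <- grepl(paste0("^", thresholds$mito_prefix), genes, ignore.case = TRUE)
  total <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mito_umi <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else 0
  pct_mito <- ifelse(total > 0, mito_umi / total, 0)
  # denominator is the configured CD3 gene count, not the number present
  cd3_mean <- Matrix::colSums(counts[cd3_present, , drop = FALSE]) /
    length(thresholds$cd3_genes)

  data.frame(barcode = colnames(counts),
             n_genes = as.integer(n_genes),
             total_umi = as.numeric(total),
             pct_mito = as.numeric(pct_mito),
             cd3_mean = as.numeric(cd3_mean),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the three-criterion cell gate
#'
#' Keeps cells with `min_genes <= n_genes <= max_genes` (inclusive),
#' `pct_mito < max_pct_mito` (strict) and `cd3_mean > min_cd3_mean` (strict).
#' Failure counts are reported per criterion independently, so one cell can
#' contribute to several counters.
#'
#' @param metrics output of [compute_cell_qc()].
#' @param thresholds a [qc_thresholds()] object.
#' @return A list with `kept` (character vector of retained barcodes, input
#'   order preserved) and `report` (list: `n_total`, `n_kept`,
#'   `fail_n_genes`, `fail_pct_mito`, `fail_cd3_mean`).
#' @export
filter_cells <- function(metrics, thresholds = qc_thresholds()) {
  stopifnot(is.data.frame(metrics),
            all(c("barcode", "n_genes", "pct_mito", "cd3_mean") %in% names(metrics)))
  ok_genes <- metrics$n_genes >= thresholds$min_genes &
    metrics$n_genes <= thresholds$max_genes
  ok_mito <- metrics$pct_mito < thresholds$max_pct_mito
  ok_cd3 <- metrics$cd3_mean > thresholds$min_cd3_mean
  keep <- ok_genes & ok_mito & ok_cd3
  list(
    kept = metrics$barcode[keep],
    report = list(
      n_total = nrow(metrics),
      n_kept = sum(keep),
      fail_n_genes = sum(!ok_genes),
      fail_pct_mito = sum(!ok_mito),
      fail_cd3_mean = sum(!ok_cd3)
    )
  )
}

#' Library-size log-normalization
#'
#' Standard single-cell "LogNormalize": each count is divided by its cell's
#' total UMI count, multiplied by `scale_factor`, and transformed with the
#' natural log1p: `value = log(1 + count / total * scale_factor)`. Zeros map
#' to zero, so the sparsity pattern is preserved.
#'
#' @param counts gene x cell count matrix; every cell must have a positive
#'   total (filter first).
#' @param scale_factor positive scale factor (default 10000, i.e. counts per
#'   ten thousand).
#' @return A `dgCMatrix` of normalized values with the same dimnames.
#' @export
log_normalize <- function(counts, scale_factor = 10000) {
  counts <- as_count_matrix(counts)
  stopifnot(scale_factor > 0)
  total <- Matrix::colSums(counts)
  if (any(total == 0)) {
    bad <- colnames(counts)[total == 0][1]
    stop("cell with zero total UMI cannot be normalized: ", bad)
  }
  norm <- counts
  # per-entry cell total, expanded along the CSC column pointer
  col_of_entry <- rep.int(seq_len(ncol(counts)), diff(counts@p))
  norm@x <- log1p(counts@x / total[col_of_entry] * scale_factor)
  norm
}
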