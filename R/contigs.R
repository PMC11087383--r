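.contig_required_cols <- c("barcode", "chain", "v_gene", "d_gene", "j_gene",
                           "cdr3", "cdr3_nt", "productive", "umis", "reads")

#' Parse a 10x-style V(D)J contig annotation table
#'
#' Accepts a `filtered_contig_annotations.csv`-compatible file (or an
#' already-read data frame) and returns one chain record per row, restricted
#' to the alpha/beta loci. Gamma/delta and other loci are dropped, with the
#' dropped count attached as attribute `n_dropped_loci`.
#'
#' The `productive` column accepts the dialects produced by different
#' pipeline versions: logical `TRUE`, or the strings `"true"/"True"/"TRUE"`.
#' Anything else (`"None"`, `"False"`, empty, `NA`) is non-productive.
#'
#' @param x path to a contig CSV, or a data frame with the same columns.
#' @return A data frame of chain records with columns `barcode`, `chain`
#'   (`TRA`/`TRB`), `v_gene`, `d_gene`, `j_gene`, `cdr3`, `cdr3_nt`,
#'   `productive` (logical), `umis`, `reads` (integer). Unknown extra columns
#'   are ignored.
#' @export
parse_contigs <- function(x) {
  df <- if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("contig file not found: ", x)
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else if (is.data.frame(x)) {
    x
  } else {
    stop("'x' must be a file path or a data frame")
  }

  missing <- setdiff(.contig_required_cols, names(df))
  if (length(missing)) {
    stop("contig table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }

  ab <- df$chain %in% c("TRA", "TRB")
  n_dropped <- sum(!ab)
  if (n_dropped > 0) {
    message(n_dropped, " contig(s) on non-alpha/beta loci dropped")
  }
  df <- df[ab, , drop = FALSE]

  for (col in c("umis", "reads")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (anyNA(v) && !all(is.na(df[[col]]) == is.na(v))) {
      bad <- which(is.na(v) & !is.na(df[[col]]))[1]
      stop(sprintf("unparseable '%s' value in contig row %d: %s",
                   col, bad, df[[col]][bad]))
    }
    if (anyNA(v)) stop(sprintf("missing '%s' value in contig table", col))
    df[[col]] <- v
  }

  prod <- df$productive
  prod <- if (is.logical(prod)) !is.na(prod) & prod else {
    !is.na(prod) & tolower(trimws(as.character(prod))) == "true"
  }

  out <- data.frame(
    barcode = as.character(df$barcode),
    chain = as.character(df$chain),
    v_gene = as.character(df$v_gene),
    d_gene = as.character(df$d_gene),
    j_gene = as.character(df$j_gene),
    cdr3 = as.character(df$cdr3),
    cdr3_nt = as.character(df$cdr3_nt),
    productive = prod,
    umis = df$umis,
    reads = df$reads,
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped_loci") <- n_dropped
  out
}

#' Resolve one productive alpha/beta pair per cell
#'
#' Non-productive chains are discarded; when a barcode retains more than one
#' chain on a locus, the winner maximizes UMIs, then reads, with the
#' lexicographically smallest CDR3 nucleotide sequence as the final
#' tie-break (a total order, so the result is independent of row order). A
#' barcode yields a pair only if both loci survive.
#'
#' @param chains chain-record data frame from [parse_contigs()].
#' @return A list with `pairs` (data frame: `barcode`, and for each chain
#'   `alpha_`/`beta_` prefixed `v_gene`, `d_gene` (beta only), `j_gene`,
#'   `cdr3`, `cdr3_nt`, `umis`, `reads`) sorted by barcode, and `report`
#'   (list: `n_barcodes`, `n_paired`, `n_unpaired`).
#' @export
resolve_paired_tcr <- function(chains) {
  stopifnot(is.data.frame(chains),
            all(c("barcode", "chain", "productive") %in% names(chains)))
  n_barcodes <- length(unique(chains$barcode))
  prod <- chains[chains$productive, , drop = FALSE]

  pick <- function(df) {
    if (nrow(df) == 0) return(df)
    ord <- order(df$barcode, -df$umis, -df$reads, df$cdr3_nt, method = "radix")
    df <- df[ord, , drop = FALSE]
    df[!duplicated(df$barcode), , drop = FALSE]
  }
  a <- pick(prod[prod$chain == "TRA", , drop = FALSE])
  b <- pick(prod[prod$chain == "TRB", , drop = FALSE])

  shared <- intersect(a$barcode, b$barcode)
  a <- a[match(shared, a$barcode), , drop = FALSE]
  b <- b[match(shared, b$barcode), , drop = FALSE]
  ord <- order(shared, method = "radix")

  pairs <- data.frame(
    barcode = shared,
    alpha_v = a$v_gene, alpha_j = a$j_gene,
    alpha_cdr3 = a$cdr3, alpha_nt = a$cdr3_nt,
    alpha_umis = a$umis, alpha_reads = a$reads,
    beta_v = b$v_gene, beta_d = b$d_gene, beta_j = b$j_gene,
    beta_cdr3 = b$cdr3, beta_nt = b$cdr3_nt,
    beta_umis = b$umis, beta_reads = b$reads,
    stringsAsFactors = FALSE
  )[ord, , drop = FALSE]
  rownames(pairs) <- NULL

  list(pairs = pairs,
       report = list(n_barcodes = n_barcodes,
                     n_paired = nrow(pairs),
                     n_unpaired = n_barcodes - nrow(pairs)))
}

#' Group paired cells into nucleotide-level clonotypes
#'
#' Cells carry the same clonotype when their alpha and beta chains are
#' identical at the nucleotide level. With `key = "cdr3nt_vj"` (default) the
#' defining key also includes the V/J (and beta D) segment names; with
#' `key = "cdr3nt_only"` only the CDR3 nucleotide sequences are compared.
#' Clonotype ids (`CT0001`, ...) are the rank of the key in the sorted key
#' set, so rebuilding from the same input reproduces identical ids.
#'
#' @param pairs paired-chain data frame from [resolve_paired_tcr()]`$pairs`
#'   (at most one row per barcode).
#' @param key clonotype key definition.
#' @return A list with `clonotypes` (data frame: `clonotype_id`, `n_cells`,
#'   `alpha_nt`, `beta_nt`, `trav`, `traj`, `cdr3_alpha`, `trbv`, `trbd`,
#'   `trbj`, `cdr3_beta`; annotations copied from the member with the
#'   lexicographically smallest barcode; sorted by decreasing `n_cells` then
#'   id) and `map` (named character vector, barcode -> clonotype_id).
#' @export
build_clonotypes <- function(pairs, key = c("cdr3nt_vj", "cdr3nt_only")) {
  key <- match.arg(key)
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1)
  if (anyDuplicated(pairs$barcode)) {
    stop("duplicate barcode(s) in paired-chain table: ",
         paste(unique(pairs$barcode[duplicated(pairs$barcode)]), collapse = ", "))
  }

  k <- if (key == "cdr3nt_vj") {
    paste(pairs$alpha_nt, pairs$alpha_v, pairs$alpha_j,
          pairs$beta_nt, pairs$beta_v, pairs$beta_d, pairs$beta_j,
          sep = "|")
  } else {
    paste(pairs$alpha_nt, pairs$beta_nt, sep = "|")
  }

  lv <- sort(unique(k))
  idx <- match(k, lv)
  ids <- sprintf("CT%0*d", max(4L, nchar(length(lv))), seq_along(lv))

  # representative member: lexicographically smallest barcode within clonotype
  ord <- order(idx, pairs$barcode, method = "radix")
  rep_row <- ord[!duplicated(idx[ord])]
  rep_idx <- idx[rep_row]

  n_cells <- tabulate(idx, nbins = length(lv))
  clon <- data.frame(
    clonotype_id = ids,
    n_cells = n_cells,
    alpha_nt = pairs$alpha_nt[rep_row][order(rep_idx)],
    beta_nt = pairs$beta_nt[rep_row][order(rep_idx)],
    trav = pairs$alpha_v[rep_row][order(rep_idx)],
    traj = pairs$alpha_j[rep_row][order(rep_idx)],
    cdr3_alpha = pairs$alpha_cdr3[rep_row][order(rep_idx)],
    trbv = pairs$beta_v[rep_row][order(rep_idx)],
    trbd = pairs$beta_d[rep_row][order(rep_idx)],
    trbj = pairs$beta_j[rep_row][order(rep_idx)],
    cdr3_beta = pairs$beta_cdr3[rep_row][order(rep_idx)],
    stringsAsFactors = FALSE
  )
  clon <- clon[order(-clon$n_cells, clon$clonotype_id), , drop = FALSE]
  rownames(clon) <- NULL

  map <- stats::setNames(ids[idx], pairs$barcode)
  list(clonotypes = clon, map = map)
}

#' Intersect expression-QC and TCR-pairing cell sets
#'
#' The final analysis set contains the cells that pass both the expression
#' gate and productive-pair resolution.
#'
#' @param expression_kept barcodes passing [filter_cells()].
#' @param paired barcodes with a resolved alpha/beta pair.
#' @return A list with `barcodes` (the intersection, in `expression_kept`
#'   order) and `report` (sizes of both inputs and of the intersection). An
#'   empty intersection is a warning, not an error.
#' @export
intersect_modalities <- function(expression_kept, paired) {
  joint <- expression_kept[expression_kept %in% paired]
  if (length(joint) == 0) {
    warning("no cells pass both expression QC and TCR pairing")
  }
  list(barcodes = joint,
       report = list(n_expression = length(expression_kept),
                     n_paired = length(paired),
                     n_joint = length(joint)))
}

#' Write a clonotype table as TSV
#'
#' @param clonotypes clonotype data frame from [build_clonotypes()].
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_clonotypes_tsv <- function(clonotypes, path) {
  utils::write.table(clonotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
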