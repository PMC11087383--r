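#' The 10-gene T cell activation signature
#'
#' Activation markers and effector molecules upregulated in recently
#' stimulated T cells: IFNG, IL2, TNF, IL2RA (CD25), CD69, TNFRSF9 (41BB),
#' GZMB, GZMA, GZMK and PRF1.
#'
#' @return Character vector of the 10 gene symbols, in canonical order.
#' @export
activation_signature <- function() {
  c("IFNG", "IL2", "TNF", "IL2RA", "CD69", "TNFRSF9",
    "GZMB", "GZMA", "GZMK", "PRF1")
}

#' Parameters for the binned-control module score
#'
#' @param n_bins number of equal-frequency expression bins (default 24).
#' @param n_ctrl control genes drawn per signature gene in stochastic mode
#'   (default 100); draws are capped at the bin size.
#' @param seed RNG seed for control-gene sampling (default 0).
#' @param mode `"stochastic"` samples controls from each signature gene's
#'   bin; `"deterministic_full_bin"` uses the whole bins (no randomness),
#'   which is convenient for exact cross-checks.
#' @return An object of class `module_score_params`.
#' @export
module_score_params <- function(n_bins = 24, n_ctrl = 100, seed = 0,
                                mode = c("stochastic", "deterministic_full_bin")) {
  mode <- match.arg(mode)
  stopifnot(n_bins >= 1, n_ctrl >= 1)
  structure(list(n_bins = n_bins, n_ctrl = n_ctrl,
                 seed = as.integer(seed), mode = mode),
            class = "module_score_params")
}

#' Bin genes by mean normalized expression
#'
#' Genes are ranked by mean normalized expression across cells (ties broken
#' by gene symbol, ascending) and the ranks cut into `n_bins` equal-frequency
#' bins whose sizes differ by at most one. Deterministic by construction.
#'
#' @param norm gene x cell normalized matrix (see [log_normalize()]).
#' @param n_bins number of bins; must not exceed the number of genes.
#' @return Named integer vector mapping every gene symbol to its bin (1 =
#'   lowest expression), in the matrix's gene order.
#' @export
bin_genes_by_mean_expression <- function(norm, n_bins = 24) {
  stopifnot(nrow(norm) >= 1, ncol(norm) >= 1)
  if (n_bins > nrow(norm)) {
    stop(sprintf("n_bins (%d) exceeds the number of genes (%d)",
                 n_bins, nrow(norm)))
  }
  means <- Matrix::rowMeans(norm)
  genes <- rownames(norm)
  ord <- order(means, genes, method = "radix")
  n <- length(genes)
  bin_sorted <- ceiling(seq_len(n) * n_bins / n)
  bins <- integer(n)
  bins[ord] <- bin_sorted
  stats::setNames(bins, genes)
}

#' Sample expression-matched control genes
#'
#' For each signature gene, controls are drawn from the gene's expression
#' bin. In stochastic mode, `min(n_ctrl, bin size)` genes are sampled
#' uniformly without replacement (signature genes are not excluded from
#' their own bins) and the draws are pooled with multiplicity. In
#' deterministic mode the control set is the union of the signature genes'
#' whole bins.
#'
#' @param bins gene -> bin map from [bin_genes_by_mean_expression()].
#' @param signature character vector of signature gene symbols (all binned).
#' @param params a [module_score_params()] object.
#' @return Character vector of control gene symbols; a multiset in
#'   stochastic mode, a sorted set in deterministic mode.
#' @export
sample_control_genes <- function(bins, signature,
                                 params = module_score_params()) {
  missing <- setdiff(signature, names(bins))
  if (length(missing)) {
    stop("signature gene(s) not present in the bin map: ",
         paste(missing, collapse = ", "))
  }
  sig_bins <- bins[signature]
  if (params$mode == "deterministic_full_bin") {
    return(sort(names(bins)[bins %in% unique(sig_bins)]))
  }
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(params$seed)
  unlist(lapply(seq_along(signature), function(i) {
    members <- sort(names(bins)[bins == sig_bins[i]])
    if (length(members) == 1) return(members)
    sample(members, min(params$n_ctrl, length(members)))
  }), use.names = FALSE)
}

#' Per-cell activation module score
#'
#' Score of a cell = mean normalized expression of the signature genes minus
#' the (multiplicity-weighted) mean normalized expression of the
#' expression-matched control genes. Matching controls by expression bin
#' removes the bias a raw signature mean would inherit from sequencing depth
#' and gene abundance; scores are centred near 0 and may be negative.
#'
#' @param norm gene x cell normalized matrix.
#' @param signature signature gene symbols; all must be present in `norm`.
#' @param params a [module_score_params()] object.
#' @return Named numeric vector of scores, aligned to `colnames(norm)`.
#' @export
compute_module_score <- function(norm, signature = activation_signature(),
                                 params = module_score_params()) {
  missing <- setdiff(signature, rownames(norm))
  if (length(missing)) {
    stop("signature gene(s) absent from the matrix: ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(signature)) stop("duplicate signature genes")
  bins <- bin_genes_by_mean_expression(norm, params$n_bins)
  ctrl <- sample_control_genes(bins, signature, params)
  sig_mean <- Matrix::colMeans(norm[signature, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm[ctrl, , drop = FALSE])
  stats::setNames(as.numeric(sig_mean - ctrl_mean), colnames(norm))
}

#' Extract one gene's normalized expression vector
#'
#' @param norm gene x cell normalized matrix.
#' @param gene gene symbol; if absent, the error suggests the closest symbol
#'   by edit distance.
#' @return Named numeric vector aligned to `colnames(norm)`.
#' @export
gene_expression <- function(norm, gene) {
  stopifnot(length(gene) == 1)
  if (!gene %in% rownames(norm)) {
    d <- utils::adist(gene, rownames(norm), ignore.case = TRUE)
    nearest <- rownames(norm)[which.min(d)]
    stop(sprintf("gene '%s' not found in the matrix; did you mean '%s'?",
                 gene, nearest))
  }
  stats::setNames(as.numeric(norm[gene, ]), colnames(norm))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}
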