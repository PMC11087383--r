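# Small in-code fixtures shared across test files.

# gene x cell count matrix from a dense integer matrix
toy_counts <- function(m, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(m)))
  if (is.null(cells)) cells <- sprintf("C%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  as_count_matrix(m)
}

# random count matrix with named genes/cells, fixed by the caller's seed
random_counts <- function(n_genes, n_cells, lambda = 2) {
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells)
  # guarantee positive cell totals so log_normalize is applicable
  m[1, ] <- m[1, ] + 1L
  toy_counts(m)
}

# one contig row in the 10x CSV dialect
contig_row <- function(barcode, chain, cdr3_nt = "TGTGCTTTT",
                       v = "TRAV1", d = "None", j = "TRAJ1",
                       cdr3 = "CAF", productive = "True",
                       umis = 5L, reads = 50L) {
  data.frame(barcode = barcode, chain = chain, v_gene = v, d_gene = d,
             j_gene = j, cdr3 = cdr3, cdr3_nt = cdr3_nt,
             productive = productive, umis = umis, reads = reads,
             stringsAsFactors = FALSE)
}

# brute-force binned-control module score: plain loops on a dense matrix,
# independent of the package's sparse/vectorized implementation
oracle_module_score <- function(norm, signature, n_bins) {
  norm <- as.matrix(norm)
  means <- apply(norm, 1, mean)
  ord <- order(means, rownames(norm), method = "radix")
  n <- nrow(norm)
  bin <- integer(n)
  bin[ord] <- ceiling(seq_len(n) * n_bins / n)
  names(bin) <- rownames(norm)
  ctrl <- character(0)
  for (b in unique(bin[signature])) {
    ctrl <- union(ctrl, rownames(norm)[bin == b])
  }
  scores <- numeric(ncol(norm))
  for (j in seq_len(ncol(norm))) {
    scores[j] <- mean(norm[signature, j]) - mean(norm[ctrl, j])
  }
  names(scores) <- colnames(norm)
  scores
}

# small simulation config used where full defaults would be slow
small_sim_config <- function(...) {
  sim_config(n_cells = 300, n_genes = 80, n_clones = 30, ...)
}

# QC thresholds loose enough for tiny simulated matrices
small_qc <- function() qc_thresholds(min_genes = 5, max_genes = 10000)
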