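#' Configuration for the synthetic stimulated-TIL dataset generator
#'
#' Defines the generative model for paired scRNA + scTCR data with known
#' reactive clones. A minority of clones is tumour-reactive; their cells turn
#' on each activation-signature gene independently with probability
#' `p_marker_on`, emulating the heterogeneous (oscillating, stochastic)
#' expression of activation markers across cells of the same reactive clone.
#' Non-reactive cells occasionally activate exactly one randomly chosen
#' signature gene (`bystander_rate`), emulating antigen-independent bystander
#' activation — the confounder that defeats single-marker ranking.
#'
#' @param n_cells total number of cells (default 3000).
#' @param n_genes total genes, including the 10 signature genes, CD3D/E/G and
#'   13 mitochondrial genes (default 2000; minimum 30).
#' @param n_clones number of T cell clones (default 300); clone weights are
#'   1 + Geometric(`p_size`), every clone receives at least one cell, and the
#'   remaining cells are assigned with probability proportional to weight.
#' @param p_size geometric parameter of the clone-size law (default 0.5).
#' @param frac_reactive fraction of clones that are reactive (default 0.05;
#'   at least one clone).
#' @param p_marker_on per-cell probability that each signature gene of a
#'   reactive cell is active (default 0.6).
#' @param bystander_rate probability that a non-reactive cell activates one
#'   random signature gene (default 0.05).
#' @param activation_fold mean-expression multiplier for active signature
#'   genes (default 8).
#' @param nb_dispersion negative-binomial dispersion of UMI counts (default
#'   0.3; variance = mu + dispersion * mu^2).
#' @param baseline_meanlog,baseline_sdlog log-normal law of per-gene baseline
#'   expression weights (defaults 0 and 1).
#' @param dropout_extra additional per-entry zero-inflation on top of the
#'   negative binomial (default 0.1).
#' @param p_unproductive_contig probability a simulated chain is flagged
#'   non-productive (default 0.1).
#' @param p_extra_chain probability a cell carries an extra decoy chain
#'   (default 0.08). Decoys have strictly lower UMI counts than the clone
#'   chain unless `equal_umi_decoys = TRUE`, in which case UMIs tie and reads
#'   are strictly lower (exercises the full tie-break cascade).
#' @param mito_shape1,mito_shape2 Beta law of the per-cell mitochondrial UMI
#'   fraction (defaults 2 and 18, mean 0.1).
#' @param target_depth expected per-cell total UMI count (default 5000).
#' @param cd3_baseline baseline expression weight assigned to CD3D/E/G so
#'   that simulated cells read as T cells (default 3).
#' @param equal_umi_decoys see `p_extra_chain`.
#' @param seed RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 3000, n_genes = 2000, n_clones = 300,
                       p_size = 0.5, frac_reactive = 0.05,
                       p_marker_on = 0.6, bystander_rate = 0.05,
                       activation_fold = 8, nb_dispersion = 0.3,
                       baseline_meanlog = 0, baseline_sdlog = 1,
                       dropout_extra = 0.1, p_unproductive_contig = 0.1,
                       p_extra_chain = 0.08, mito_shape1 = 2,
                       mito_shape2 = 18, target_depth = 5000,
                       cd3_baseline = 3, equal_umi_decoys = FALSE,
                       seed = 1) {
  probs <- c(p_size = p_size, frac_reactive = frac_reactive,
             p_marker_on = p_marker_on, bystander_rate = bystander_rate,
             dropout_extra = dropout_extra,
             p_unproductive_contig = p_unproductive_contig,
             p_extra_chain = p_extra_chain)
  if (any(probs < 0 | probs > 1)) {
    stop("probability parameter(s) outside [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  if (n_genes < 30) stop("n_genes must be at least 30")
  if (round(frac_reactive * n_clones) < 1) {
    stop("frac_reactive * n_clones must round to at least one reactive clone")
  }
  if (n_cells < n_clones) stop("n_cells must be at least n_clones")
  stopifnot(activation_fold > 0, nb_dispersion > 0, target_depth > 0,
            cd3_baseline > 0, mito_shape1 > 0, mito_shape2 > 0,
            p_size > 0)
  structure(
    list(n_cells = n_cells, n_genes = n_genes, n_clones = n_clones,
         p_size = p_size, frac_reactive = frac_reactive,
         p_marker_on = p_marker_on, bystander_rate = bystander_rate,
         activation_fold = activation_fold, nb_dispersion = nb_dispersion,
         baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
         dropout_extra = dropout_extra,
         p_unproductive_contig = p_unproductive_contig,
         p_extra_chain = p_extra_chain,
         mito_shape1 = mito_shape1, mito_shape2 = mito_shape2,
         target_depth = target_depth, cd3_baseline = cd3_baseline,
         equal_umi_decoys = equal_umi_decoys, seed = as.integer(seed)),
    class = "sim_config")
}

.mito_gene_names <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8",
                      "MT-ATP6", "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4",
                      "MT-ND5", "MT-ND6", "MT-CYB")
.cd3_gene_names <- c("CD3D", "CD3E", "CD3G")
.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
# one fixed codon per amino acid: back-translation is deterministic given
# the amino-acid string, and lengths stay divisible by 3
.codon_of <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
               G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
               M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
               S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

.random_cdr3 <- function(n, min_len = 10, max_len = 16) {
  len <- sample(min_len:max_len, n, replace = TRUE)
  vapply(len, function(l) {
    paste0("C", paste(sample(.aa_alphabet, l - 2, replace = TRUE),
                      collapse = ""), "F")
  }, character(1))
}

.back_translate <- function(aa) {
  vapply(strsplit(aa, ""), function(ch) {
    paste(.codon_of[ch], collapse = "")
  }, character(1))
}

#' Simulate a paired scRNA + scTCR stimulated-TIL dataset
#'
#' Draws clones, cells, UMI counts and V(D)J contigs from the generative
#' model in [sim_config()] and records the ground truth, which serves as the
#' oracle for ranking-recovery evaluation. The count matrix and contig table
#' use exactly the dialects consumed by [read_counts_10x()] /
#' [parse_contigs()], so the simulator output round-trips through the
#' pipeline's own readers and writers.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `til_simulation`: a list with
#'   \describe{
#'     \item{counts}{sparse gene x cell UMI matrix.}
#'     \item{contigs}{contig annotation data frame (10x CSV dialect, with
#'       `productive` as `"True"`/`"None"` strings).}
#'     \item{truth}{list with `cell_clone` (barcode -> clone id),
#'       `clones` (data frame: `clone_id`, `reactive`, `n_cells`,
#'       `alpha_nt`, `beta_nt` and segment annotations), `decoy_nt`
#'       (CDR3 nucleotide sequences of simulated decoy chains — clonotypes
#'       containing one arise when a decoy outcompetes a non-productive
#'       primary chain and are non-reactive by construction) and
#'       `active_markers` (signature x cell logical matrix).}
#'   }
#' @export
simulate_til_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(config$seed)

  sig <- activation_signature()
  n_filler <- config$n_genes - length(sig) - length(.cd3_gene_names) -
    length(.mito_gene_names)
  genes <- c(sig, .cd3_gene_names, .mito_gene_names,
             sprintf("GENE%04d", seq_len(n_filler)))
  barcodes <- sprintf("CELL%05d", seq_len(config$n_cells))
  mito <- genes %in% .mito_gene_names

  ## --- clones and cell assignment -------------------------------------
  clone_ids <- sprintf("CLONE%03d", seq_len(config$n_clones))
  weights <- 1 + stats::rgeom(config$n_clones, config$p_size)
  assign <- c(seq_len(config$n_clones),
              sample(config$n_clones, config$n_cells - config$n_clones,
                     replace = TRUE, prob = weights))
  assign <- sample(assign)
  n_reactive <- max(1L, as.integer(round(config$frac_reactive * config$n_clones)))
  reactive_clones <- sample(config$n_clones, n_reactive)
  clone_reactive <- seq_len(config$n_clones) %in% reactive_clones
  cell_reactive <- clone_reactive[assign]

  ## --- activation structure -------------------------------------------
  active <- matrix(FALSE, length(sig), config$n_cells,
                   dimnames = list(sig, barcodes))
  if (any(cell_reactive)) {
    active[, cell_reactive] <-
      stats::runif(length(sig) * sum(cell_reactive)) < config$p_marker_on
  }
  nr <- which(!cell_reactive)
  bystander <- nr[stats::runif(length(nr)) < config$bystander_rate]
  if (length(bystander)) {
    gene_pick <- sample(length(sig), length(bystander), replace = TRUE)
    active[cbind(gene_pick, bystander)] <- TRUE
  }

  ## --- expression means and counts ------------------------------------
  w <- stats::rlnorm(config$n_genes, config$baseline_meanlog,
                     config$baseline_sdlog)
  names(w) <- genes
  w[.cd3_gene_names] <- config$cd3_baseline
  W <- matrix(w, config$n_genes, config$n_cells)
  W[seq_along(sig), ][active] <-
    W[seq_along(sig), ][active] * config$activation_fold

  f <- stats::rbeta(config$n_cells, config$mito_shape1, config$mito_shape2)
  mu <- W
  nonmito_sum <- colSums(W[!mito, , drop = FALSE])
  mu[!mito, ] <- sweep(W[!mito, , drop = FALSE], 2,
                       (1 - f) * config$target_depth / nonmito_sum, `*`)
  mu[mito, ] <- outer(w[mito] / sum(w[mito]),
                      f * config$target_depth)

  counts <- stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
  if (config$dropout_extra > 0) {
    counts[stats::runif(length(counts)) < config$dropout_extra] <- 0L
  }
  counts <- matrix(counts, config$n_genes, config$n_cells,
                   dimnames = list(genes, barcodes))
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")

  ## --- TCR chains per clone -------------------------------------------
  repeat {
    alpha_aa <- .random_cdr3(config$n_clones)
    beta_aa <- .random_cdr3(config$n_clones)
    if (!anyDuplicated(paste(alpha_aa, beta_aa))) break
  }
  alpha_nt <- .back_translate(alpha_aa)
  beta_nt <- .back_translate(beta_aa)
  i <- seq_len(config$n_clones) - 1L
  clones <- data.frame(
    clone_id = clone_ids, reactive = clone_reactive,
    n_cells = tabulate(assign, config$n_clones),
    trav = paste0("TRAV", i %% 45 + 1), traj = paste0("TRAJ", i %% 50 + 1),
    alpha_cdr3 = alpha_aa, alpha_nt = alpha_nt,
    trbv = paste0("TRBV", i %% 30 + 1),
    trbd = c("TRBD1", "TRBD2")[i %% 2 + 1],
    trbj = paste0("TRBJ", i %% 13 + 1),
    beta_cdr3 = beta_aa, beta_nt = beta_nt,
    stringsAsFactors = FALSE)

  ## --- contig rows ------------------------------------------------------
  umis_a <- 2L + stats::rpois(config$n_cells, 6)
  umis_b <- 2L + stats::rpois(config$n_cells, 6)
  reads_a <- umis_a * (3L + stats::rpois(config$n_cells, 4))
  reads_b <- umis_b * (3L + stats::rpois(config$n_cells, 4))
  prod_a <- ifelse(stats::runif(config$n_cells) < config$p_unproductive_contig,
                   "None", "True")
  prod_b <- ifelse(stats::runif(config$n_cells) < config$p_unproductive_contig,
                   "None", "True")
  cl <- clones[assign, ]

  contig_a <- data.frame(
    barcode = barcodes, chain = "TRA",
    v_gene = cl$trav, d_gene = "None", j_gene = cl$traj,
    cdr3 = cl$alpha_cdr3, cdr3_nt = cl$alpha_nt,
    productive = prod_a, umis = umis_a, reads = reads_a,
    stringsAsFactors = FALSE)
  contig_b <- data.frame(
    barcode = barcodes, chain = "TRB",
    v_gene = cl$trbv, d_gene = cl$trbd, j_gene = cl$trbj,
    cdr3 = cl$beta_cdr3, cdr3_nt = cl$beta_nt,
    productive = prod_b, umis = umis_b, reads = reads_b,
    stringsAsFactors = FALSE)

  has_decoy <- which(stats::runif(config$n_cells) < config$p_extra_chain)
  contigs <- rbind(contig_a, contig_b)
  if (length(has_decoy)) {
    d_chain <- sample(c("TRA", "TRB"), length(has_decoy), replace = TRUE)
    d_aa <- .random_cdr3(length(has_decoy))
    d_primary_umis <- ifelse(d_chain == "TRA", umis_a[has_decoy],
                             umis_b[has_decoy])
    d_primary_reads <- ifelse(d_chain == "TRA", reads_a[has_decoy],
                              reads_b[has_decoy])
    if (config$equal_umi_decoys) {
      d_umis <- d_primary_umis
      d_reads <- pmax(1L, d_primary_reads -
                        1L - stats::rpois(length(has_decoy), 5))
    } else {
      d_umis <- pmax(1L, d_primary_umis - 1L -
                       stats::rpois(length(has_decoy), 2))
      d_reads <- d_umis * (3L + stats::rpois(length(has_decoy), 4))
    }
    j <- seq_along(has_decoy) - 1L
    decoys <- data.frame(
      barcode = barcodes[has_decoy], chain = d_chain,
      v_gene = ifelse(d_chain == "TRA", paste0("TRAV", j %% 45 + 1),
                      paste0("TRBV", j %% 30 + 1)),
      d_gene = ifelse(d_chain == "TRA", "None",
                      c("TRBD1", "TRBD2")[j %% 2 + 1]),
      j_gene = ifelse(d_chain == "TRA", paste0("TRAJ", j %% 50 + 1),
                      paste0("TRBJ", j %% 13 + 1)),
      cdr3 = d_aa, cdr3_nt = .back_translate(d_aa),
      productive = "True", umis = d_umis, reads = d_reads,
      stringsAsFactors = FALSE)
    contigs <- rbind(contigs, decoys)
  }
  contigs <- contigs[order(contigs$barcode, contigs$chain,
                           method = "radix"), , drop = FALSE]
  rownames(contigs) <- NULL

  structure(
    list(counts = counts, contigs = contigs,
         truth = list(
           cell_clone = stats::setNames(clone_ids[assign], barcodes),
           clones = clones,
           decoy_nt = if (length(has_decoy)) unique(decoys$cdr3_nt)
                      else character(0),
           active_markers = active),
         config = config),
    class = "til_simulation")
}

#' Write a contig annotation table as CSV
#'
#' @param contigs contig data frame (as produced by [simulate_til_dataset()]).
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_contigs_csv <- function(contigs, path) {
  utils::write.csv(contigs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
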