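#' Screen stimulated TILs for candidate tumour-reactive TCRs
#'
#' Runs the full screening pipeline on one paired dataset:
#' \enumerate{
#'   \item per-cell QC on raw counts and the three-criterion cell gate
#'     (gene-count window, mitochondrial fraction, mean CD3 UMI);
#'   \item productive alpha/beta chain resolution and nucleotide-level
#'     clonotype assembly from the contig annotations;
#'   \item intersection of the two modalities into the final analysis set;
#'   \item log-normalization and per-cell statistics on that set: normalized
#'     IFNG and TNFRSF9 expression and the 10-gene activation module score;
#'   \item clonotype-level averaging (clonotypes on fewer than `min_cells`
#'     cells are excluded from ranking), ranking under each key, and
#'     selection of the deduplicated top-`k`-per-key candidate panel.
#' }
#'
#' @param counts gene x cell UMI count matrix (see [read_counts_10x()]), or a
#'   path to a 10x matrix directory.
#' @param contigs contig annotation table (data frame or CSV path, see
#'   [parse_contigs()]).
#' @param thresholds [qc_thresholds()] for the expression gate.
#' @param signature activation signature gene symbols (default
#'   [activation_signature()]).
#' @param score_params [module_score_params()] for the module score.
#' @param min_cells minimum clone size for ranking (default 3).
#' @param k candidates selected per ranking key (default 3).
#' @param clonotype_key clonotype definition, see [build_clonotypes()].
#' @return An object of class `tcr_screen`: a list with `cell_scores`
#'   (per-cell table: `barcode`, `IFNG`, `TNFRSF9`, `activation_score`),
#'   `clonotypes` (clonotype annotation table), `clonotype_scores` (full
#'   per-clonotype means with per-key ranks), `ranked` (list of the three
#'   ranked eligible tables), `panel` (the [select_candidate_panel()]
#'   result, annotated with chain information), `reports` (QC, pairing and
#'   intersection reports) and the parameters used.
#' @seealso [simulate_til_dataset()] to generate inputs with known truth,
#'   [run_benchmark()] for ranking-recovery evaluation.
#' @examples
#' sim <- simulate_til_dataset(sim_config(n_cells = 400, n_genes = 120,
#'                                        n_clones = 40, seed = 7))
#' scr <- screen_tcrs(sim$counts, sim$contigs,
#'                    thresholds = qc_thresholds(min_genes = 10))
#' scr
#' head(scr$panel)
#' @export
screen_tcrs <- function(counts, contigs,
                        thresholds = qc_thresholds(),
                        signature = activation_signature(),
                        score_params = module_score_params(),
                        min_cells = 3, k = 3,
                        clonotype_key = c("cdr3nt_vj", "cdr3nt_only")) {
  clonotype_key <- match.arg(clonotype_key)
  if (is.character(counts)) counts <- read_counts_10x(counts)
  counts <- as_count_matrix(counts)
  chains <- parse_contigs(contigs)

  # expression gate
  qc <- compute_cell_qc(counts, thresholds)
  flt <- filter_cells(qc, thresholds)

  # TCR gate
  paired <- resolve_paired_tcr(chains)

  # joint analysis set
  joint <- intersect_modalities(flt$kept, paired$pairs$barcode)
  if (length(joint$barcodes) == 0) {
    stop("no cells pass both modalities; nothing to screen")
  }

  # clonotypes over the joint set
  pairs_joint <- paired$pairs[paired$pairs$barcode %in% joint$barcodes, ,
                              drop = FALSE]
  clon <- build_clonotypes(pairs_joint, key = clonotype_key)

  # per-cell statistics on the joint set
  norm <- log_normalize(counts[, joint$barcodes, drop = FALSE],
                        thresholds$scale_factor)
  score <- compute_module_score(norm, signature, score_params)
  cell_scores <- data.frame(
    barcode = joint$barcodes,
    IFNG = gene_expression(norm, "IFNG"),
    TNFRSF9 = gene_expression(norm, "TNFRSF9"),
    activation_score = as.numeric(score),
    row.names = NULL, stringsAsFactors = FALSE)

  # clonotype-level aggregation, ranking, panel
  cst <- clonotype_score_table(cell_scores, clon$map, min_cells = min_cells)
  ranked <- lapply(cst$ranked, function(tab) {
    merge_cols <- c("clonotype_id", "alpha_nt", "beta_nt", "trav", "traj",
                    "cdr3_alpha", "trbv", "trbd", "trbj", "cdr3_beta")
    cbind(tab, clon$clonotypes[match(tab$clonotype_id,
                                     clon$clonotypes$clonotype_id),
                               setdiff(merge_cols, names(tab)),
                               drop = FALSE])
  })
  panel <- select_candidate_panel(ranked, k = k)
  ann <- clon$clonotypes[match(panel$clonotype_id,
                               clon$clonotypes$clonotype_id),
                         c("n_cells", "trav", "traj", "cdr3_alpha",
                           "trbv", "trbd", "trbj", "cdr3_beta"),
                         drop = FALSE]
  panel_ann <- cbind(as.data.frame(panel), ann, row.names = NULL)
  class(panel_ann) <- c("candidate_panel", "data.frame")
  attr(panel_ann, "k") <- k

  structure(
    list(cell_scores = cell_scores,
         clonotypes = clon$clonotypes,
         clonotype_map = clon$map,
         clonotype_scores = cst$table,
         ranked = ranked,
         panel = panel_ann,
         reports = list(qc = flt$report, pairing = paired$report,
                        joint = joint$report,
                        n_clonotypes = nrow(clon$clonotypes),
                        n_expanded = sum(clon$clonotypes$n_cells >= 2),
                        n_eligible = sum(cst$table$in_ranking)),
         params = list(thresholds = thresholds, signature = signature,
                       score_params = score_params, min_cells = min_cells,
                       k = k, clonotype_key = clonotype_key)),
    class = "tcr_screen")
}

#' @export
print.tcr_screen <- function(x, ...) {
  r <- x$reports
  cat("Tumour-reactive TCR screen\n")
  cat(sprintf("  cells: %d assayed, %d pass expression QC, %d paired, %d joint\n",
              r$qc$n_total, r$qc$n_kept, r$pairing$n_paired, r$joint$n_joint))
  cat(sprintf("  clonotypes: %d total, %d on >=2 cells, %d eligible (>= %d cells)\n",
              r$n_clonotypes, r$n_expanded, r$n_eligible, x$params$min_cells))
  cat(sprintf("  candidate panel: %d TCR(s) (top %d per key, deduplicated)\n",
              nrow(x$panel), x$params$k))
  invisible(x)
}

#' @export
summary.tcr_screen <- function(object, ...) {
  print(object)
  cat("\nCandidate panel:\n")
  print(as.data.frame(object$panel)[, c("clonotype_id", "selected_by",
                                        "best_rank", "n_cells", "trav",
                                        "traj", "trbv", "trbj")],
        row.names = FALSE)
  invisible(object)
}

#' Plot clonotype-level marker means against the activation score
#'
#' Scatter of the clonotype mean IFNG expression (x) versus the clonotype
#' mean activation score (y) over the ranking-eligible set, with panel
#' members highlighted. Visualizes why single-marker and combined-score
#' rankings can disagree.
#'
#' @param x a `tcr_screen` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tcr_screen <- function(x, ...) {
  tab <- x$clonotype_scores[x$clonotype_scores$in_ranking, , drop = FALSE]
  in_panel <- tab$clonotype_id %in% x$panel$clonotype_id
  graphics::plot(tab$mean_ifng, tab$mean_activation,
                 pch = ifelse(in_panel, 19, 1),
                 col = ifelse(in_panel, "firebrick", "grey40"),
                 xlab = "clonotype mean normalized IFNG",
                 ylab = "clonotype mean activation score", ...)
  graphics::legend("topleft", pch = c(19, 1),
                   col = c("firebrick", "grey40"),
                   legend = c("candidate panel", "other clonotypes"),
                   bty = "n")
  invisible(x)
}

#' @export
print.candidate_panel <- function(x, ...) {
  cat(sprintf("Candidate TCR panel: %d entries (k = %s per key)\n",
              nrow(x), attr(x, "k")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
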