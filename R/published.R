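#' The published two-patient candidate TCR table
#'
#' The characteristics of the candidate TCRs reported by the lung
#' adenocarcinoma TIL screen this package operationalizes: for each patient,
#' the top three clonotypes by mean normalized IFNG, by mean normalized
#' TNFRSF9 and by mean activation score, with their V/D/J segment calls,
#' CDR3 amino-acid sequences, cell counts and the published per-key values.
#' Shipped as plain text in `inst/extdata/til_candidate_tcrs.tsv`.
#'
#' Two cell-count/rank fields were ambiguous in the published layout and are
#' transcribed per this package's reading (they do not affect chain
#' identity, which is what the panel-selection example uses).
#'
#' @return Data frame with one row per (patient, group, rank) selection.
#' @export
til_candidate_table <- function() {
  path <- system.file("extdata", "til_candidate_tcrs.tsv",
                      package = "reactivetcr", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Ranked tables from the published candidate table
#'
#' Reshapes one patient's rows of [til_candidate_table()] into the ranked
#' tables consumed by [select_candidate_panel()]. Clonotype identity is the
#' full chain annotation (V/J segments plus CDR3 of both chains), since the
#' published table reports no nucleotide sequences.
#'
#' @param patient `"P1"` or `"P2"`.
#' @param groups which ranking keys to include (default the two single
#'   markers, matching the screen's first selection round).
#' @param table the candidate table (defaults to the shipped one).
#' @return Named list of ranked tables (`clonotype_id`, `n_cells`, `mean`,
#'   `rank`), one per group.
#' @export
published_ranked_tables <- function(patient,
                                    groups = c("IFNG", "TNFRSF9"),
                                    table = til_candidate_table()) {
  stopifnot(patient %in% table$patient)
  value_col <- c(IFNG = "norm_ifng", TNFRSF9 = "norm_tnfrsf9",
                 SCORE = "activation_score")
  out <- lapply(groups, function(g) {
    rows <- table[table$patient == patient & table$group == g, , drop = FALSE]
    if (nrow(rows) == 0) stop("no rows for patient ", patient, ", group ", g)
    data.frame(
      clonotype_id = paste(rows$trav, rows$traj, rows$cdr3_alpha,
                           rows$trbv, rows$trbd, rows$trbj, rows$cdr3_beta,
                           sep = "|"),
      n_cells = rows$n_cells,
      mean = rows[[value_col[[g]]]],
      rank = rows$rank_in_group,
      stringsAsFactors = FALSE)
  })
  names(out) <- groups
  out
}
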