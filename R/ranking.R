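#' Aggregate a per-cell value to clonotype means
#'
#' Averages a barcode-aligned per-cell vector (a marker's normalized
#' expression, or the activation score) over the member cells of each
#' clonotype. Clonotypes carried by fewer than `min_cells` cells stay in the
#' returned table but are flagged out of the ranking set: averaging over very
#' few cells makes single bystander-activated cells look like reactive
#' clones, so small clones are excluded from ranking.
#'
#' @param values named numeric vector (names = barcodes).
#' @param map named character vector, barcode -> clonotype_id (from
#'   [build_clonotypes()]). Barcodes in `values` without a map entry are
#'   dropped with a message; it is an error if none remain.
#' @param min_cells minimum clone size for ranking eligibility (default 3).
#' @return Data frame: `clonotype_id`, `n_cells`, `mean`, `in_ranking`
#'   (logical), sorted by `clonotype_id`.
#' @export
aggregate_by_clonotype <- function(values, map, min_cells = 3) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  mapped <- names(values) %in% names(map)
  if (!any(mapped)) {
    stop("no barcode in 'values' has a clonotype assignment")
  }
  if (any(!mapped)) {
    message(sum(!mapped), " barcode(s) without clonotype assignment dropped")
  }
  v <- values[mapped]
  id <- unname(map[names(v)])
  means <- tapply(v, id, mean)
  sizes <- tapply(v, id, length)
  out <- data.frame(clonotype_id = names(means),
                    n_cells = as.integer(sizes),
                    mean = as.numeric(means),
                    stringsAsFactors = FALSE)
  out <- out[order(out$clonotype_id), , drop = FALSE]
  out$in_ranking <- out$n_cells >= min_cells
  rownames(out) <- NULL
  out
}

#' Rank clonotypes by a mean statistic
#'
#' Orders descending by `mean`; ties are broken by `n_cells` descending, then
#' `clonotype_id` ascending, giving a total order — ranks 1..N are a
#' permutation and the result is invariant to input row order.
#'
#' @param table data frame with columns `clonotype_id`, `n_cells`, `mean`
#'   (typically [aggregate_by_clonotype()] restricted to `in_ranking` rows).
#' @return The table sorted into rank order with an integer `rank` column
#'   prepended values 1..N.
#' @export
rank_clonotypes <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("clonotype_id", "n_cells", "mean") %in% names(table)))
  if (nrow(table) == 0) stop("cannot rank an empty clonotype table")
  ord <- order(-table$mean, -table$n_cells, table$clonotype_id,
               method = "radix")
  out <- table[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select the deduplicated candidate TCR panel
#'
#' Takes the top `k` clonotypes from each ranking key and merges them by
#' clonotype id: a clonotype selected under several keys yields one panel
#' entry carrying all its selecting keys. This reproduces the screening
#' design in which the top 3 by IFNG, by TNFRSF9 and by activation score are
#' pooled, and identical TCRs are synthesized once.
#'
#' @param ranked named list of ranked tables from [rank_clonotypes()]; names
#'   are the key labels (e.g. `IFNG`, `TNFRSF9`, `SCORE`).
#' @param k selections per key (default 3). If a table has fewer than `k`
#'   rows, all its rows are taken with a warning.
#' @return An object of class `candidate_panel`: a data frame with
#'   `clonotype_id`, `selected_by` (comma-separated key labels), `best_rank`,
#'   and one `rank_<key>` column per key, ordered by (`best_rank`,
#'   `clonotype_id`). Panel size lies in `[k, length(ranked) * k]` when every
#'   table has at least `k` rows.
#' @export
select_candidate_panel <- function(ranked, k = 3) {
  stopifnot(is.list(ranked), length(ranked) >= 1, !is.null(names(ranked)))
  top <- lapply(names(ranked), function(key) {
    tab <- ranked[[key]]
    stopifnot(all(c("clonotype_id", "rank") %in% names(tab)))
    if (nrow(tab) < k) {
      warning(sprintf("ranking '%s' has only %d clonotype(s); taking all",
                      key, nrow(tab)))
    }
    head(tab[order(tab$rank), , drop = FALSE], k)
  })
  names(top) <- names(ranked)

  ids <- sort(unique(unlist(lapply(top, `[[`, "clonotype_id"))))
  panel <- data.frame(clonotype_id = ids, stringsAsFactors = FALSE)
  sel <- matrix(FALSE, nrow = length(ids), ncol = length(ranked),
                dimnames = list(ids, names(ranked)))
  for (key in names(ranked)) {
    sel[top[[key]]$clonotype_id, key] <- TRUE
    panel[[paste0("rank_", key)]] <-
      ranked[[key]]$rank[match(ids, ranked[[key]]$clonotype_id)]
  }
  panel$selected_by <- apply(sel, 1, function(r) {
    paste(names(ranked)[r], collapse = ",")
  })
  rank_cols <- paste0("rank_", names(ranked))
  panel$best_rank <- do.call(pmin, c(panel[rank_cols], list(na.rm = TRUE)))
  panel <- panel[order(panel$best_rank, panel$clonotype_id), , drop = FALSE]
  rownames(panel) <- NULL
  panel <- panel[, c("clonotype_id", "selected_by", "best_rank", rank_cols)]
  class(panel) <- c("candidate_panel", "data.frame")
  attr(panel, "k") <- k
  panel
}

#' Build the per-clonotype score table used for ranking
#'
#' Convenience wrapper aggregating the three per-cell statistics (IFNG,
#' TNFRSF9, activation score) to clonotype level and attaching per-key ranks
#' computed over the ranking-eligible (`n_cells >= min_cells`) set.
#'
#' @param cell_scores data frame with columns `barcode`, `IFNG`, `TNFRSF9`,
#'   `activation_score`.
#' @param map barcode -> clonotype_id map.
#' @param min_cells minimum clone size for ranking eligibility.
#' @return A list with `table` (full clonotype table: `clonotype_id`,
#'   `n_cells`, `mean_ifng`, `mean_tnfrsf9`, `mean_activation`,
#'   `in_ranking`, and `rank_IFNG`/`rank_TNFRSF9`/`rank_SCORE` over the
#'   eligible set, NA otherwise) and `ranked` (named list of the three
#'   ranked eligible tables, keys `IFNG`, `TNFRSF9`, `SCORE`).
#' @export
clonotype_score_table <- function(cell_scores, map, min_cells = 3) {
  stopifnot(all(c("barcode", "IFNG", "TNFRSF9", "activation_score")
                %in% names(cell_scores)))
  cols <- c(IFNG = "IFNG", TNFRSF9 = "TNFRSF9", SCORE = "activation_score")
  aggs <- lapply(cols, function(col) {
    aggregate_by_clonotype(
      stats::setNames(cell_scores[[col]], cell_scores$barcode),
      map, min_cells = min_cells)
  })
  tab <- data.frame(clonotype_id = aggs$IFNG$clonotype_id,
                    n_cells = aggs$IFNG$n_cells,
                    mean_ifng = aggs$IFNG$mean,
                    mean_tnfrsf9 = aggs$TNFRSF9$mean,
                    mean_activation = aggs$SCORE$mean,
                    in_ranking = aggs$IFNG$in_ranking,
                    stringsAsFactors = FALSE)
  ranked <- lapply(names(cols), function(key) {
    rank_clonotypes(aggs[[key]][aggs[[key]]$in_ranking, , drop = FALSE])
  })
  names(ranked) <- names(cols)
  for (key in names(cols)) {
    tab[[paste0("rank_", key)]] <-
      ranked[[key]]$rank[match(tab$clonotype_id, ranked[[key]]$clonotype_id)]
  }
  list(table = tab, ranked = ranked)
}
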