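test_that("clonotype aggregation averages members and flags small clones", {
  values <- setNames(c(0.5, 0.7, 0.9, 0.2, 0.4, 1.0),
                     c("b1", "b2", "b3", "b4", "b5", "unmapped"))
  map <- setNames(c("CT1", "CT1", "CT1", "CT2", "CT2"),
                  c("b1", "b2", "b3", "b4", "b5"))

  expect_message(agg <- aggregate_by_clonotype(values, map, min_cells = 3),
                 "1 barcode")
  expect_equal(agg$mean[agg$clonotype_id == "CT1"], 0.7)
  expect_true(agg$in_ranking[agg$clonotype_id == "CT1"])
  expect_false(agg$in_ranking[agg$clonotype_id == "CT2"])  # 2 cells < 3
  expect_equal(sum(agg$n_cells), 5)                        # cell conservation

  # degenerate: everything in one clonotype
  one <- aggregate_by_clonotype(values[1:5], setNames(rep("CT", 5), names(values)[1:5]))
  expect_equal(one$mean, mean(values[1:5]))

  expect_error(aggregate_by_clonotype(values["unmapped"], map), "no barcode")
})

test_that("ranking is a deterministic total order with documented tie-breaks", {
  tab <- data.frame(clonotype_id = c("CTa", "CTb", "CTc", "CTd"),
                    n_cells = c(3L, 5L, 3L, 4L),
                    mean = c(0.9, 0.9, 0.2, 0.2))
  r <- rank_clonotypes(tab)
  # tie on mean broken by size; then by id
  expect_equal(r$clonotype_id, c("CTb", "CTa", "CTd", "CTc"))
  expect_equal(r$rank, 1:4)

  # permutation invariance and re-rank identity
  for (i in 1:5) {
    rp <- rank_clonotypes(tab[sample(nrow(tab)), ])
    expect_identical(rp, r)
  }
  expect_identical(rank_clonotypes(r)[names(r)], r[names(r)])

  # positive scaling leaves ranks unchanged
  scaled <- tab; scaled$mean <- scaled$mean * 17.3
  expect_identical(rank_clonotypes(scaled)$clonotype_id, r$clonotype_id)

  expect_equal(rank_clonotypes(tab[2, ])$rank, 1)
  expect_error(rank_clonotypes(tab[0, ]), "empty")
})

test_that("panel selection merges overlapping top-k across keys", {
  mk <- function(ids) data.frame(clonotype_id = ids,
                                 n_cells = rep(3L, length(ids)),
                                 mean = rev(seq_along(ids)),
                                 rank = seq_along(ids),
                                 stringsAsFactors = FALSE)
  universe <- paste0("CT", 1:9)

  # three disjoint top-3 sets -> 9 entries
  disj <- select_candidate_panel(list(IFNG = mk(universe[1:3]),
                                      TNFRSF9 = mk(universe[4:6]),
                                      SCORE = mk(universe[7:9])), k = 3)
  expect_equal(nrow(disj), 9)

  # identical rankings -> exactly k entries, each selected by all keys
  same <- select_candidate_panel(list(IFNG = mk(universe),
                                      TNFRSF9 = mk(universe),
                                      SCORE = mk(universe)), k = 3)
  expect_equal(nrow(same), 3)
  expect_true(all(same$selected_by == "IFNG,TNFRSF9,SCORE"))

  # k larger than the table: take all with a warning
  expect_warning(short <- select_candidate_panel(list(IFNG = mk(universe[1:2])),
                                                 k = 3),
                 "only 2")
  expect_equal(nrow(short), 2)
})

test_that("per-key score table carries consistent ranks over the eligible set", {
  set.seed(13)
  barcodes <- sprintf("b%02d", 1:20)
  cell_scores <- data.frame(barcode = barcodes,
                            IFNG = runif(20), TNFRSF9 = runif(20),
                            activation_score = rnorm(20))
  map <- setNames(paste0("CT", rep(1:6, c(5, 4, 3, 3, 3, 2))), barcodes)
  res <- clonotype_score_table(cell_scores, map, min_cells = 3)

  expect_equal(sum(res$table$n_cells), 20)
  expect_equal(sum(res$table$in_ranking), 5)      # the 2-cell clone drops out
  for (key in c("IFNG", "TNFRSF9", "SCORE")) {
    ranks <- res$table[[paste0("rank_", key)]]
    expect_setequal(ranks[!is.na(ranks)], 1:5)    # permutation over eligibles
    expect_true(all(is.na(ranks[!res$table$in_ranking])))
  }
})
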