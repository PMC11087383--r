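test_that("simulation is deterministic given (config, seed) and conserves cells", {
  cfg <- small_sim_config(seed = 17)
  s1 <- simulate_til_dataset(cfg)
  s2 <- simulate_til_dataset(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$contigs, s2$contigs)
  expect_identical(s1$truth, s2$truth)

  # different seed changes the data
  s3 <- simulate_til_dataset(small_sim_config(seed = 18))
  expect_false(identical(s1$counts, s3$counts))

  # truth conservation: every cell maps to exactly one clone, sizes add up
  expect_setequal(names(s1$truth$cell_clone), colnames(s1$counts))
  expect_equal(sum(s1$truth$clones$n_cells), cfg$n_cells)
  expect_equal(as.vector(table(s1$truth$cell_clone)[s1$truth$clones$clone_id]),
               s1$truth$clones$n_cells)
  expect_equal(sum(s1$truth$clones$reactive),
               round(cfg$frac_reactive * cfg$n_clones))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(p_marker_on = 1.2), "p_marker_on")
  expect_error(sim_config(n_genes = 20), "at least 30")
  expect_error(sim_config(frac_reactive = 0.001), "reactive clone")
  expect_error(sim_config(n_cells = 10, n_clones = 50), "n_clones")
})

test_that("noise-free limit: the single reactive clone dominates every signature gene", {
  cfg <- small_sim_config(frac_reactive = 1 / 30, p_marker_on = 1,
                          bystander_rate = 0, dropout_extra = 0,
                          nb_dispersion = 1e-4, activation_fold = 50,
                          p_unproductive_contig = 0, p_extra_chain = 0,
                          seed = 5)
  sim <- simulate_til_dataset(cfg)
  reactive_clone <- sim$truth$clones$clone_id[sim$truth$clones$reactive]
  clone_of <- sim$truth$cell_clone[colnames(sim$counts)]
  for (g in activation_signature()) {
    means <- tapply(as.numeric(sim$counts[g, ]), clone_of, mean)
    expect_equal(names(which.max(means)), reactive_clone)
  }
})

test_that("UMI counts match the negative-binomial target marginally", {
  # neutral genes, no activation in non-reactive cells, no extra dropout
  cfg <- sim_config(n_cells = 4000, n_genes = 60, n_clones = 40,
                    frac_reactive = 1 / 40, bystander_rate = 0,
                    dropout_extra = 0, mito_shape2 = 1e6,  # mito share ~ 0
                    seed = 91)
  sim <- simulate_til_dataset(cfg)
  non_reactive <- names(sim$truth$cell_clone)[
    !sim$truth$clones$reactive[match(sim$truth$cell_clone,
                                     sim$truth$clones$clone_id)]]
  x <- sim$counts[, non_reactive]
  neutral <- setdiff(rownames(x), c(activation_signature(), "CD3D", "CD3E",
                                    "CD3G"))[1:20]
  for (g in neutral) {
    v <- as.numeric(x[g, ])
    mu_hat <- mean(v)
    # NB variance: mu + dispersion * mu^2; allow generous sampling slack
    expect_equal(var(v), mu_hat + cfg$nb_dispersion * mu_hat^2,
                 tolerance = 0.25)
  }
})

test_that("paired-cell yield matches the closed-form productive-pair expectation", {
  # both chains must be productive: expected yield (1 - p_unproductive)^2
  cfg <- small_sim_config(p_extra_chain = 0, seed = 1)
  yields <- vapply(1:20, function(i) {
    cfg$seed <- i
    sim <- simulate_til_dataset(cfg)
    resolve_paired_tcr(parse_contigs(sim$contigs))$report$n_paired
  }, numeric(1))
  expected <- cfg$n_cells * (1 - cfg$p_unproductive_contig)^2
  # binomial tolerance over 20 x 300 cells: ~4 sd of the pooled mean
  se <- sqrt(cfg$n_cells * 0.81 * 0.19 / 20)
  expect_lt(abs(mean(yields) - expected), 4 * se)
})

test_that("decoy chains never displace the clone chain when UMIs are strictly lower", {
  cfg <- small_sim_config(p_unproductive_contig = 0, p_extra_chain = 0.5,
                          seed = 23)
  sim <- simulate_til_dataset(cfg)
  pairs <- resolve_paired_tcr(parse_contigs(sim$contigs))$pairs
  clone_of <- sim$truth$cell_clone[pairs$barcode]
  idx <- match(clone_of, sim$truth$clones$clone_id)
  expect_identical(pairs$alpha_nt, sim$truth$clones$alpha_nt[idx])
  expect_identical(pairs$beta_nt, sim$truth$clones$beta_nt[idx])
})

test_that("simulated outputs round-trip through the package's own readers", {
  sim <- simulate_til_dataset(small_sim_config(seed = 8))
  dir <- tempfile("tenx")
  write_counts_10x(sim$counts, dir)
  expect_equal(read_counts_10x(dir), sim$counts)

  dirgz <- tempfile("tenxgz")
  write_counts_10x(sim$counts, dirgz, gzip = TRUE)
  expect_equal(read_counts_10x(dirgz), sim$counts)

  csv <- tempfile(fileext = ".csv")
  write_contigs_csv(sim$contigs, csv)
  expect_identical(parse_contigs(csv), parse_contigs(sim$contigs))
})

test_that("ranking evaluation counts reactive clonotypes in the top k", {
  clonotypes <- data.frame(clonotype_id = paste0("CT", 1:5),
                           alpha_nt = paste0("A", 1:5),
                           beta_nt = paste0("B", 1:5))
  truth <- list(clones = data.frame(clone_id = paste0("CL", 1:5),
                                    alpha_nt = paste0("A", 1:5),
                                    beta_nt = paste0("B", 1:5),
                                    reactive = c(TRUE, FALSE, TRUE, FALSE, FALSE)),
                decoy_nt = character(0))
  ranked <- list(KEY = data.frame(clonotype_id = paste0("CT", c(1, 2, 3, 4, 5)),
                                  rank = 1:5))
  ev <- evaluate_ranking(ranked, clonotypes, truth, k = 3)
  expect_equal(ev$precision_at_k, 2 / 3)   # CT1, CT3 reactive in top 3
  expect_equal(ev$reciprocal_rank, 1)

  # all reactive -> precision 1; none in top k -> 0
  truth$clones$reactive <- rep(TRUE, 5)
  expect_equal(evaluate_ranking(ranked, clonotypes, truth, 3)$precision_at_k, 1)
  truth$clones$reactive <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  ev0 <- evaluate_ranking(ranked, clonotypes, truth, 3)
  expect_equal(ev0$precision_at_k, 0)
  expect_equal(ev0$reciprocal_rank, 1 / 4)

  # clonotype absent from truth is an error
  clonotypes$alpha_nt[1] <- "FOREIGN"
  expect_error(evaluate_ranking(ranked, clonotypes, truth, 3), "CT1")
})

test_that("a one-seed benchmark equals that seed's metrics", {
  cfg <- small_sim_config(seed = 33)
  bm <- run_benchmark(cfg, n_seeds = 1, thresholds = small_qc())
  sim <- simulate_til_dataset(cfg)
  scr <- screen_tcrs(sim$counts, sim$contigs, thresholds = small_qc())
  ev <- evaluate_ranking(scr$ranked, scr$clonotypes, sim$truth, k = 3)
  expect_equal(bm$summary$mean_precision_at_k,
               ev$precision_at_k[match(bm$summary$key, ev$key)])
})
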