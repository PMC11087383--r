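norm_toy <- function(m, ...) log_normalize(toy_counts(m, ...))

test_that("equal-frequency binning ranks by mean with lexicographic ties", {
  # 4 genes, 2 bins: lowest-mean pair in bin 1
  m <- norm_toy(matrix(c(5L, 1L, 3L, 7L), 4, 3), genes = c("A", "B", "C", "D"))
  bins <- bin_genes_by_mean_expression(m, 2)
  expect_equal(bins, c(A = 2L, B = 1L, C = 1L, D = 2L))

  # all means identical: assignment fully determined by symbol order
  m2 <- norm_toy(matrix(2L, 4, 2), genes = c("D", "B", "A", "C"))
  expect_equal(bin_genes_by_mean_expression(m2, 2),
               c(D = 2L, B = 1L, A = 1L, C = 2L))

  # 25 genes in 24 bins: twenty-three singletons and one pair
  m3 <- norm_toy(matrix(rpois(25 * 4, 3) + 1L, 25, 4))
  sizes <- table(bin_genes_by_mean_expression(m3, 24))
  expect_equal(sort(as.integer(sizes)), c(rep(1L, 23), 2L))

  expect_error(bin_genes_by_mean_expression(m3, 26), "exceeds")
})

test_that("control sampling is seeded, capped at bin size, and counts multiplicity", {
  set.seed(11)
  m <- norm_toy(matrix(rpois(50 * 6, 2) + 1L, 50, 6))
  bins <- bin_genes_by_mean_expression(m, 10)   # bins of 5
  sig <- names(bins)[seq(1, 50, by = 5)]        # 10 genes, distinct bins

  p <- module_score_params(n_bins = 10, n_ctrl = 3, seed = 42)
  ctrl1 <- sample_control_genes(bins, sig, p)
  ctrl2 <- sample_control_genes(bins, sig, p)
  expect_identical(ctrl1, ctrl2)                # same seed, same draw
  expect_length(ctrl1, 30)                      # 10 genes x min(3, 5)

  # n_ctrl >= bin size: stochastic equals the full-bin union as a set
  pfull <- module_score_params(n_bins = 10, n_ctrl = 100, seed = 0)
  det <- sample_control_genes(bins, sig,
                              module_score_params(n_bins = 10,
                                                  mode = "deterministic_full_bin"))
  expect_setequal(sample_control_genes(bins, sig, pfull), det)

  expect_error(sample_control_genes(bins, "NOT_A_GENE", p), "NOT_A_GENE")
})

test_that("deterministic module score equals the brute-force oracle", {
  set.seed(2024)
  for (rep in 1:30) {
    n_genes <- sample(12:50, 1)
    n_cells <- sample(3:30, 1)
    m <- random_counts(n_genes, n_cells)
    rownames(m)[1:10] <- activation_signature()
    norm <- log_normalize(m)
    n_bins <- sample(1:5, 1)
    got <- compute_module_score(
      norm, params = module_score_params(n_bins = n_bins,
                                         mode = "deterministic_full_bin"))
    expect_equal(got, oracle_module_score(norm, activation_signature(), n_bins),
                 tolerance = 1e-12)
  }
})

test_that("module score analytic limits: flat matrices score zero, per-cell shifts cancel", {
  # every gene identical within each cell -> signature mean == control mean
  m <- Matrix::Matrix(rep(c(1, 2, 4), each = 15), 15, 3, sparse = TRUE,
                      dimnames = list(c(activation_signature(),
                                        sprintf("G%02d", 1:5)),
                                      c("c1", "c2", "c3")))
  for (mode in c("stochastic", "deterministic_full_bin")) {
    sc <- compute_module_score(m, params = module_score_params(n_bins = 3,
                                                               mode = mode))
    expect_equal(unname(sc), c(0, 0, 0))
  }

  # adding a constant to ALL genes of one cell leaves every score unchanged
  set.seed(5)
  m2 <- as.matrix(log_normalize(random_counts(20, 6)))
  rownames(m2)[1:10] <- activation_signature()
  m2 <- Matrix::Matrix(m2, sparse = TRUE)
  shifted <- m2
  shifted[, 2] <- shifted[, 2] + 3.7
  for (mode in c("stochastic", "deterministic_full_bin")) {
    p <- module_score_params(n_bins = 4, mode = mode)
    expect_equal(compute_module_score(m2, params = p),
                 compute_module_score(shifted, params = p),
                 tolerance = 1e-12)
  }
})

test_that("single-gene signature in an otherwise silent bin has closed-form score", {
  # gene g plus 5 all-zero genes form one bin of m = 6;
  # control = whole bin, so score = norm(g) * (1 - 1/m)
  counts <- matrix(0L, 6, 3)
  counts[6, ] <- c(2L, 5L, 9L)
  m <- toy_counts(counts, genes = c(sprintf("Z%d", 1:5), "g"))
  norm <- log_normalize(m)
  sc <- compute_module_score(norm, signature = "g",
                             params = module_score_params(n_bins = 1,
                                                          n_ctrl = 50))
  expect_equal(unname(sc), as.numeric(norm["g", ]) * (1 - 1 / 6),
               tolerance = 1e-12)
})

test_that("stochastic scores are reproducible and invariant to axis permutations", {
  set.seed(9)
  m <- log_normalize(random_counts(30, 12))
  p <- module_score_params(n_bins = 6, n_ctrl = 2, seed = 3)
  sig <- rownames(m)[c(4, 9, 17)]
  s1 <- compute_module_score(m, sig, p)
  s2 <- compute_module_score(m, sig, p)
  expect_identical(s1, s2)

  gp <- sample(nrow(m)); cp <- sample(ncol(m))
  s3 <- compute_module_score(m[gp, cp], sig, p)
  expect_equal(s3[names(s1)], s1, tolerance = 1e-12)
})

test_that("single-gene extraction matches the normalized row and suggests near-misses", {
  m <- log_normalize(random_counts(12, 5))
  rownames(m)[3] <- "IFNG"
  expect_equal(gene_expression(m, "IFNG"),
               setNames(as.numeric(m["IFNG", ]), colnames(m)))
  expect_error(gene_expression(m, "IFNGG"), "IFNG")
  expect_error(compute_module_score(m, c("IFNG", "NOPE1", "NOPE2")),
               "NOPE1, NOPE2")
})
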