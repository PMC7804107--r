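test_that("qc_filter applies detected-gene bounds and gene prevalence", {
  m <- matrix(0L, 3, 8000,
              dimnames = list(paste0("c", 1:3), paste0("g", 1:8000)))
  m[1, 1:10] <- 1L       # 10 detected genes
  m[2, 1:500] <- 1L      # 500
  m[3, 1:6000] <- 1L     # 6000
  cm <- count_matrix(m, "stimA")
  kept <- qc_filter(cm, min_genes_per_cell = 200, max_genes_per_cell = 5000,
                    min_cells_per_gene = 1)
  expect_identical(cell_ids(kept), "c2")

  # identity thresholds return the input unchanged
  ident <- qc_filter(cm, min_genes_per_cell = 0, max_genes_per_cell = Inf,
                     min_cells_per_gene = 0)
  expect_equal(as.matrix(ident$counts), m)

  expect_error(qc_filter(cm, min_genes_per_cell = 7000,
                         max_genes_per_cell = 8000),
               "All cells filtered")
})

test_that("qc_filter removes planted dead cells at min_genes = 1", {
  sim <- small_sim(seed = 31, n = 100)
  m <- as.matrix(sim$counts$counts)
  dead <- sample(nrow(m), ceiling(0.05 * nrow(m)))
  m[dead, ] <- 0L
  cm <- count_matrix(m, sim$counts$condition)
  kept <- qc_filter(cm, min_genes_per_cell = 1, max_genes_per_cell = Inf,
                    min_cells_per_gene = 0)
  expect_identical(sort(setdiff(rownames(m), cell_ids(kept))),
                   sort(rownames(m)[dead]))
})

test_that("normalization matches the closed form and is scale invariant", {
  m <- matrix(c(2L, 0L, 4L, 2L, 1L, 5L), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("g1", "g2")))
  norm <- normalize_counts(count_matrix(m, "control"))
  # totals 2, 6, 6 -> median 6 -> size factors 1/3, 1, 1
  expect_equal(unname(norm$size_factors), c(1 / 3, 1, 1))
  expect_equal(median(norm$size_factors), 1)
  expect_equal(as.numeric(norm$values["a", ]), c(log(7), 0))
  expect_equal(as.numeric(norm$values["b", ]), c(log(5), log(3)))

  # size factors are ratios to the median total, so scaling every cell by
  # the same constant leaves them unchanged and the values follow the
  # hand-recomputed closed form on the scaled counts
  norm10 <- normalize_counts(count_matrix(m * 10L, "control"))
  expect_equal(norm10$size_factors, norm$size_factors)
  expect_equal(as.numeric(norm10$values["a", ]), c(log(61), 0))

  m0 <- m; m0[1, ] <- 0L
  expect_error(normalize_counts(count_matrix(m0, "control")), "a")
})

test_that("rank-sum p-values agree with wilcox.test and handle ties", {
  withr::local_seed(7)
  x <- matrix(c(rnbinom(120, mu = 2, size = 0.5),
                rep(1, 120),                       # constant gene
                sample(0:3, 120, replace = TRUE)), ncol = 3)
  grp <- rep(c(TRUE, FALSE), each = 20)[seq_len(40)]
  p_pkg <- costimr:::ranksum_p(x[1:40, ], grp)
  for (j in c(1, 3)) {
    p_ref <- suppressWarnings(
      wilcox.test(x[1:40, j][grp], x[1:40, j][!grp],
                  exact = FALSE, correct = TRUE)$p.value)
    expect_equal(p_pkg[j], p_ref, tolerance = 1e-10)
  }
  expect_equal(p_pkg[2], 1)   # all tied
})

test_that("differential expression is well calibrated on a null split", {
  sim <- small_sim(seed = 17, n = 300)
  m <- as.matrix(sim$counts$counts)
  ctrl <- m[sim$counts$condition == "control", ]
  cond <- rep(c("h1", "h2"), length.out = nrow(ctrl))
  norm <- normalize_counts(count_matrix(ctrl, cond))
  de <- differential_expression(norm, "h1", "h2")
  expect_gt(mean(de$p_value < 0.05), 0.015)
  expect_lt(mean(de$p_value < 0.05), 0.10)
  expect_lte(sum(de$fdr <= 0.05), 1)
  expect_true(all(de$direction[de$fdr > 0.05] == "ns"))
})

test_that("differential expression recovers planted 4-fold genes", {
  sim <- simulate_counts(count_sim_params(
    n_cells_per_condition = 500, n_genes = 500, n_program_genes_A = 50,
    n_program_genes_B = 50, n_shared_genes = 20, dispersion = 0.5, seed = 23))
  norm <- normalize_counts(sim$counts)
  de <- differential_expression(norm, "stimA", "control")
  planted <- sim$truth$genes$gene_id[sim$truth$genes$program == "A"]
  calls <- de$gene[de$direction == "up"]
  expect_gte(mean(planted %in% calls), 0.95)
  expect_error(differential_expression(norm, "nope", "control"), "Unknown")
})

test_that("DE is symmetric: swapping groups inverts fold change, keeps p", {
  sim <- small_sim(seed = 29, n = 80)
  norm <- normalize_counts(sim$counts)
  fwd <- differential_expression(norm, "stimA", "control")
  rev <- differential_expression(norm, "control", "stimA")
  expect_equal(rev$p_value, fwd$p_value, tolerance = 1e-12)
  # fold changes invert up to the epsilon pseudocount
  expressed <- fwd$frac_expressed_test > 0.2 & fwd$frac_expressed_ref > 0.2
  expect_equal(rev$fold_change[expressed], 1 / fwd$fold_change[expressed],
               tolerance = 1e-4)
  expect_identical(rev$direction[fwd$direction == "up"],
                   rep("down", sum(fwd$direction == "up")))
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  withr::local_seed(5)
  for (i in 1:25) {
    p <- runif(sample(3:20, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("core-gene selection applies all three thresholds at the boundary", {
  de <- tibble::tibble(
    gene = c("fc_low", "frac_low", "ok", "fdr_high"),
    fold_change = c(1.49, 2.0, 1.5, 3.0),
    p_value = c(0.001, 0.001, 0.001, 0.04),
    fdr = c(0.01, 0.04, 0.05, 0.051),
    frac_expressed_test = c(0.9, 0.14, 0.15, 0.9),
    frac_expressed_ref = c(0.1, 0.1, 0.1, 0.1),
    direction = c("ns", "up", "up", "ns"))
  expect_identical(define_core_genes(de), "ok")
})

test_that("core-gene selection is monotone in its thresholds", {
  sim <- small_sim(seed = 41, n = 120)
  de <- differential_expression(normalize_counts(sim$counts),
                                "stimA", "control")
  base <- define_core_genes(de)
  expect_true(all(base %in% define_core_genes(de, fc_min = 1.2)))
  expect_true(all(base %in% define_core_genes(de, fdr_max = 0.2)))
  expect_true(all(base %in% define_core_genes(de, frac_min = 0.05)))
})

test_that("planted core genes are recovered with high sensitivity, low FP", {
  sim <- simulate_counts(count_sim_params(
    n_cells_per_condition = 500, n_genes = 500, n_program_genes_A = 50,
    n_program_genes_B = 50, n_shared_genes = 20, seed = 13))
  norm <- normalize_counts(sim$counts)
  core_A <- define_core_genes(differential_expression(norm, "stimA", "control"))
  genes <- sim$truth$genes
  planted <- genes$gene_id[genes$program %in% c("A", "shared")]
  background <- genes$gene_id[genes$program %in% c("none", "B")]
  expect_gte(mean(planted %in% core_A), 0.95)
  expect_lte(mean(background %in% core_A), 0.01)
})

test_that("program set algebra yields disjoint UCG and shared sets", {
  ps <- derive_program_sets(c("g1", "g2", "g3"), c("g2", "g4"))
  expect_identical(ps$shared, "g2")
  expect_identical(ps$ucg_A, c("g1", "g3"))
  expect_identical(ps$ucg_B, "g4")
  expect_length(intersect(ps$ucg_A, ps$ucg_B), 0)
  expect_identical(length(ps$core_A), length(ps$ucg_A) + length(ps$shared))

  same <- derive_program_sets(c("a", "b"), c("a", "b"))
  expect_length(same$ucg_A, 0)
  expect_length(same$ucg_B, 0)

  # constructed overlap is counted exactly
  a <- paste0("g", 1:1141)
  b <- c(paste0("g", 1:95), paste0("h", 1:285))
  expect_length(derive_program_sets(a, b)$shared, 95)
})

test_that("cross-regulation labels recover planted inhibition", {
  # strong inhibition of program B in an A-dominant-rich costim population
  sim <- simulate_counts(count_sim_params(
    n_cells_per_condition = 400, n_genes = 300, n_program_genes_A = 40,
    n_program_genes_B = 40, n_shared_genes = 10, cross_inhibition = 0.2,
    costim_fractions = c(0.8, 0.1, 0.1), seed = 19))
  norm <- normalize_counts(sim$counts)
  ps <- derive_program_sets(
    define_core_genes(differential_expression(norm, "stimA", "control")),
    define_core_genes(differential_expression(norm, "stimB", "control")))
  ps <- classify_cross_regulation(norm, ps)
  cr_B <- ps$cross_regulation[ps$cross_regulation$program == "B", ]
  expect_gt(mean(cr_B$label == "inhibited"), 0.5)

  # no inhibition: nearly everything unchanged
  sim1 <- simulate_counts(count_sim_params(
    n_cells_per_condition = 400, n_genes = 300, n_program_genes_A = 40,
    n_program_genes_B = 40, n_shared_genes = 10, cross_inhibition = 1,
    costim_fractions = c(0, 0, 1), seed = 20))
  norm1 <- normalize_counts(sim1$counts)
  ps1 <- derive_program_sets(
    define_core_genes(differential_expression(norm1, "stimA", "control")),
    define_core_genes(differential_expression(norm1, "stimB", "control")))
  ps1 <- classify_cross_regulation(norm1, ps1)
  expect_gte(mean(ps1$cross_regulation$label == "unchanged"), 0.95)
})
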