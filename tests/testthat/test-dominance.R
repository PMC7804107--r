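# shared small training scenario: strong 4-fold programs, no inhibition
dominance_sim <- function(seed = 50, n = 250, fractions = c(0.45, 0.45, 0.10),
                          ci = 0) {
  simulate_counts(count_sim_params(
    n_cells_per_condition = n, n_genes = 200, n_program_genes_A = 40,
    n_program_genes_B = 40, n_shared_genes = 10, cross_inhibition = ci,
    costim_fractions = fractions, seed = seed))
}

test_that("config validation enforces the three-layer tanh architecture", {
  expect_error(classifier_config(hidden_layers = c(10, 10)), "three hidden")
  expect_error(classifier_config(train_fraction = 1), "0, 1")
  expect_error(classifier_config(cv_folds = 1), "at least 2")
})

test_that("training is reproducible and reports sane accuracies", {
  sim <- dominance_sim()
  norm <- normalize_counts(sim$counts)
  cfg <- classifier_config(seed = 3, run_cv = FALSE, epochs = 25)
  m1 <- train_ovr(norm, cfg)
  m2 <- train_ovr(norm, cfg)
  expect_identical(m1$net_A$layers, m2$net_A$layers)
  expect_identical(m1$report, m2$report)
  expect_true(all(m1$report$accuracy_holdout >= 0.95))
  expect_true(all(m1$report$accuracy_holdout <= 1))
  g <- glance(m1)
  expect_identical(g$n_features, 200L)
})

test_that("held-out accuracy collapses to chance on shuffled labels", {
  sim <- dominance_sim(seed = 51, n = 400)
  m <- as.matrix(sim$counts$counts)
  cond <- sim$counts$condition
  single <- cond %in% c("stimA", "stimB")
  shuffled <- cond
  shuffled[single] <- withr::with_seed(9, sample(cond[single]))
  norm <- normalize_counts(count_matrix(m, shuffled))
  model <- train_ovr(norm, classifier_config(seed = 2, run_cv = FALSE,
                                             epochs = 25))
  expect_lt(abs(min(model$report$accuracy_holdout) - 0.5), 0.07)
  expect_lt(abs(max(model$report$accuracy_holdout) - 0.5), 0.07)
})

test_that("single-stimulus-like cells are confidently assigned their program", {
  sim <- dominance_sim(seed = 52, n = 400)
  norm <- normalize_counts(sim$counts)
  model <- train_ovr(norm, classifier_config(seed = 4, run_cv = FALSE,
                                             epochs = 30))
  # score the held-in stimA cells themselves: drawn exactly from the
  # stimulus-A generative model
  labels <- classify_costim(model, norm, condition = "stimA")
  expect_gte(mean(labels$label == "A-dominant"), 0.99)
})

test_that("labels partition cells, permute with input order, and respect a
           degenerate threshold", {
  sim <- dominance_sim(seed = 53)
  norm <- normalize_counts(sim$counts)
  model <- train_ovr(norm, classifier_config(seed = 5, run_cv = FALSE,
                                             epochs = 25))
  labels <- classify_costim(model, norm)
  n_costim <- sum(norm$condition == "costim")
  expect_identical(nrow(labels), n_costim)
  expect_false(anyNA(labels$label))
  expect_identical(sum(table(labels$label)), n_costim)

  # permuting cell order permutes labels identically
  perm <- withr::with_seed(2, sample(length(norm$condition)))
  m_perm <- as.matrix(sim$counts$counts)[perm, ]
  norm_perm <- normalize_counts(count_matrix(m_perm,
                                             sim$counts$condition[perm]))
  labels_perm <- classify_costim(model, norm_perm)
  expect_identical(
    labels_perm$label[match(labels$cell_id, labels_perm$cell_id)],
    labels$label)

  # threshold 1.0: no probability reaches it, everything unclassified
  all_un <- classify_costim(model, norm, decision_threshold = 1.0)
  expect_true(all(all_un$label == "unclassified"))
})

test_that("planted dominant fractions are recovered on UCG features", {
  # program sizes matter here: the per-gene NB overlap at 4-fold induction
  # leaves a few percent Bayes error below ~50 features per program
  sim <- simulate_counts(count_sim_params(
    n_cells_per_condition = 1000, n_genes = 400, n_program_genes_A = 100,
    n_program_genes_B = 100, n_shared_genes = 0, cross_inhibition = 0,
    costim_fractions = c(0.45, 0.45, 0.10), seed = 54))
  norm <- normalize_counts(sim$counts)
  ps <- derive_program_sets(
    define_core_genes(differential_expression(norm, "stimA", "control")),
    define_core_genes(differential_expression(norm, "stimB", "control")))
  ps <- classify_cross_regulation(norm, ps)
  cfg <- classifier_config(feature_set = "cross_inhibited_ucgs", seed = 6,
                           run_cv = FALSE, epochs = 40,
                           include_controls = TRUE)
  model <- train_ovr(norm, cfg, program = ps)
  labels <- classify_costim(model, norm)
  frac <- as.numeric(table(labels$label)) / nrow(labels)
  truth_frac <- c(0.45, 0.45, 0.10, 0)
  expect_true(all(abs(frac - truth_frac) <= 0.05))
})

test_that("feature-set comparison finds the expected modal labels", {
  # mixed-only population: both programs fully induced in every costim cell
  sim <- simulate_counts(count_sim_params(
    n_cells_per_condition = 400, n_genes = 300, n_program_genes_A = 60,
    n_program_genes_B = 60, n_shared_genes = 20, cross_inhibition = 1,
    costim_fractions = c(0, 0, 1), seed = 55))
  norm <- normalize_counts(sim$counts)
  genes <- sim$truth$genes
  ps <- derive_program_sets(genes$gene_id[genes$program %in% c("A", "shared")],
                            genes$gene_id[genes$program %in% c("B", "shared")])
  ps <- classify_cross_regulation(norm, ps)
  cfg <- classifier_config(seed = 7, run_cv = FALSE, epochs = 25,
                           include_controls = TRUE)
  cmp <- suppressWarnings(compare_feature_sets(norm, ps, cfg))
  expect_identical(as.character(cmp$label[which.max(cmp$n_all_genes)]),
                   "mixed")
  # on UCG-only features a calibrated one-vs-rest classifier cannot place a
  # fully mixed cell in either single-stimulus class (the likelihood ratio
  # between the classes is symmetric there), so the modal label is mixed
  # or unclassified, never a dominant call
  expect_true(as.character(cmp$label[which.max(cmp$n_cross_inhibited_ucgs)])
              %in% c("mixed", "unclassified"))

  # dominant-rich population: dominant labels outnumber mixed + unclassified
  sim2 <- dominance_sim(seed = 56, n = 300, fractions = c(0.5, 0.5, 0),
                        ci = 0.1)
  norm2 <- normalize_counts(sim2$counts)
  ps2 <- derive_program_sets(
    define_core_genes(differential_expression(norm2, "stimA", "control")),
    define_core_genes(differential_expression(norm2, "stimB", "control")))
  ps2 <- classify_cross_regulation(norm2, ps2)
  cmp2 <- compare_feature_sets(norm2, ps2, cfg)
  dominant <- sum(cmp2$n_cross_inhibited_ucgs[cmp2$label %in%
                                                c("A-dominant", "B-dominant")])
  rest <- sum(cmp2$n_cross_inhibited_ucgs[cmp2$label %in%
                                            c("mixed", "unclassified")])
  expect_gt(dominant, rest)

  # empty costim condition: empty table plus warning
  single_only <- sim2$counts$condition != "costim"
  m3 <- as.matrix(sim2$counts$counts)[single_only, ]
  norm3 <- normalize_counts(count_matrix(m3,
                                         sim2$counts$condition[single_only]))
  expect_warning(out <- compare_feature_sets(norm3, ps2, cfg), "No co-stim")
  expect_identical(nrow(out), 0L)
})

test_that("training accuracy is at least held-out accuracy in the median", {
  accs <- vapply(1:6, function(s) {
    sim <- dominance_sim(seed = 60 + s, n = 100)
    norm <- normalize_counts(sim$counts)
    cfg <- classifier_config(seed = s, run_cv = FALSE, epochs = 15)
    model <- train_ovr(norm, cfg)
    # recompute training accuracy from the stored nets
    universe <- norm$condition %in% c("stimA", "stimB")
    X <- as.matrix(norm$values[universe, model$features])
    X <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
    y <- norm$condition[universe] == "stimA"
    train_acc <- mean((costimr:::mlp_prob(model$net_A, X) >= 0.5) == y)
    train_acc - min(model$report$accuracy_holdout)
  }, numeric(1))
  expect_gte(median(accs), 0)
})

test_that("classifier round trips through its text serialization", {
  sim <- dominance_sim(seed = 57, n = 120)
  norm <- normalize_counts(sim$counts)
  model <- train_ovr(norm, classifier_config(seed = 8, run_cv = FALSE,
                                             epochs = 10))
  f <- withr::local_tempfile(fileext = ".txt")
  write_classifier(model, f)
  back <- read_classifier(f)
  l1 <- classify_costim(model, norm)
  l2 <- classify_costim(back, norm)
  expect_equal(l2$p_A, l1$p_A, tolerance = 1e-12)
  expect_identical(l2$label, l1$label)
})
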