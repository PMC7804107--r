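#' Parameters for the negative-binomial count simulator
#'
#' Defines a four-condition experiment (control, stimA, stimB, costim) with
#' two partially overlapping stimulus-induced gene programs. Counts are
#' negative binomial with mean mu and variance mu + mu^2/dispersion.
#' Co-stimulated cells are a mixture of A-dominant, B-dominant and mixed
#' cells; in a dominant cell the opposing program's induced mean is scaled
#' by `cross_inhibition` (1 = no inhibition, 0 = full silencing of the
#' induced component, i.e. the gene falls back to baseline).
#'
#' Default values describe the reference simulation used throughout the
#' package's own checks: moderately expressed genes (baseline mean 0.5
#' UMI), strong 4-fold induction, dispersion 0.5 (variance well above
#' Poisson), and a co-stimulated population dominated by specialized cells.
#'
#' @param n_cells_per_condition Cells per condition.
#' @param n_genes Total genes; program blocks are carved from the front.
#' @param n_program_genes_A,n_program_genes_B,n_shared_genes Sizes of the
#'   disjoint program blocks (A-only, B-only, shared).
#' @param baseline_mean NB mean of unstimulated genes (UMI).
#' @param induction_fold_A,induction_fold_B Fold induction (>= 1) of
#'   program genes under their own stimulus.
#' @param dispersion NB shape parameter; variance = mu + mu^2/dispersion.
#' @param costim_fractions Numeric triple (A-dominant, B-dominant, mixed)
#'   summing to 1.
#' @param cross_inhibition Multiplier in \[0, 1\] applied to the opposing
#'   program's induced component in dominant cells.
#' @param seed Integer seed; the same parameters and seed always produce
#'   byte-identical output.
#' @return A validated `count_sim_params` list.
#' @export
count_sim_params <- function(n_cells_per_condition = 1000,
                             n_genes = 1000,
                             n_program_genes_A = 200,
                             n_program_genes_B = 200,
                             n_shared_genes = 50,
                             baseline_mean = 0.5,
                             induction_fold_A = 4,
                             induction_fold_B = 4,
                             dispersion = 0.5,
                             costim_fractions = c(0.45, 0.45, 0.10),
                             cross_inhibition = 0.2,
                             seed = 1L) {
  p <- list(n_cells_per_condition = as.integer(n_cells_per_condition),
            n_genes = as.integer(n_genes),
            n_program_genes_A = as.integer(n_program_genes_A),
            n_program_genes_B = as.integer(n_program_genes_B),
            n_shared_genes = as.integer(n_shared_genes),
            baseline_mean = baseline_mean,
            induction_fold_A = induction_fold_A,
            induction_fold_B = induction_fold_B,
            dispersion = dispersion,
            costim_fractions = as.numeric(costim_fractions),
            cross_inhibition = cross_inhibition,
            seed = as.integer(seed))
  for (f in c("n_cells_per_condition", "n_genes", "n_program_genes_A",
              "n_program_genes_B", "n_shared_genes")) {
    if (p[[f]] < 0L || (f %in% c("n_cells_per_condition", "n_genes") && p[[f]] <= 0L)) {
      abort(sprintf("`%s` must be positive.", f))
    }
  }
  if (p$n_program_genes_A + p$n_program_genes_B + p$n_shared_genes > p$n_genes) {
    abort("Program gene blocks must fit inside `n_genes` (disjoint blocks).")
  }
  assert_positive_scalar(p$baseline_mean, "baseline_mean")
  assert_positive_scalar(p$dispersion, "dispersion")
  if (p$induction_fold_A < 1 || p$induction_fold_B < 1) {
    abort("Induction folds must be >= 1.")
  }
  if (length(p$costim_fractions) != 3L || any(p$costim_fractions < 0) ||
      abs(sum(p$costim_fractions) - 1) > 1e-9) {
    abort("`costim_fractions` must be three non-negative numbers summing to 1.")
  }
  if (p$cross_inhibition < 0 || p$cross_inhibition > 1) {
    abort("`cross_inhibition` must lie in [0, 1].")
  }
  structure(p, class = "count_sim_params")
}

# Deterministic integer split of n cells into the three costim states.
split_costim <- function(n, fractions) {
  counts <- floor(n * fractions)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(n * fractions - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  counts
}

#' Simulate a planted-truth UMI count matrix
#'
#' Draws negative-binomial counts for four conditions. Program genes are
#' induced by their own stimulus; shared genes are induced by either
#' stimulus at the geometric mean of the two folds; in co-stimulated
#' dominant cells the opposing program's induced component is scaled by
#' `cross_inhibition`, while mixed cells induce both programs fully.
#'
#' @param params A [count_sim_params()].
#' @return A list with `counts` (a [count_matrix()]) and `truth`, itself a
#'   list of two tibbles: `cells` (cell_id, condition, state) and `genes`
#'   (gene_id, program, induced fold per stimulus).
#' @examples
#' sim <- simulate_counts(count_sim_params(n_cells_per_condition = 50,
#'                                         n_genes = 60,
#'                                         n_program_genes_A = 10,
#'                                         n_program_genes_B = 10,
#'                                         n_shared_genes = 5, seed = 7))
#' table(sim$truth$cells$state)
#' @export
simulate_counts <- function(params) {
  stopifnot(inherits(params, "count_sim_params"))
  p <- params
  nA <- p$n_program_genes_A; nB <- p$n_program_genes_B; nS <- p$n_shared_genes
  program <- rep(c("A", "B", "shared", "none"),
                 c(nA, nB, nS, p$n_genes - nA - nB - nS))
  gene_id <- sprintf("gene%0*d", nchar(p$n_genes), seq_len(p$n_genes))
  fold_shared <- sqrt(p$induction_fold_A * p$induction_fold_B)

  # Per-cell states in a fixed order; costim states assigned
  # deterministically so planted fractions are exact.
  n <- p$n_cells_per_condition
  n_costim <- split_costim(n, p$costim_fractions)
  state <- c(rep("control", n), rep("A", n), rep("B", n),
             rep(c("costim:A-dominant", "costim:B-dominant", "costim:mixed"),
                 n_costim))
  condition <- c(rep("control", n), rep("stimA", n), rep("stimB", n),
                 rep("costim", n))
  n_cells <- length(state)
  cell_id <- sprintf("cell%0*d", nchar(n_cells), seq_len(n_cells))

  # Mean for each (state, program class); induced component of the
  # opposing program scaled by cross_inhibition in dominant cells.
  b <- p$baseline_mean
  fA <- p$induction_fold_A; fB <- p$induction_fold_B; ci <- p$cross_inhibition
  mu_for <- function(st) {
    mu <- rep(b, p$n_genes)
    amp_A <- program == "A"; amp_B <- program == "B"; amp_S <- program == "shared"
    if (st == "A") {
      mu[amp_A] <- b * fA; mu[amp_S] <- b * fold_shared
    } else if (st == "B") {
      mu[amp_B] <- b * fB; mu[amp_S] <- b * fold_shared
    } else if (st == "costim:A-dominant") {
      mu[amp_A] <- b * fA
      mu[amp_B] <- b * (1 + (fB - 1) * ci)
      mu[amp_S] <- b * fold_shared
    } else if (st == "costim:B-dominant") {
      mu[amp_B] <- b * fB
      mu[amp_A] <- b * (1 + (fA - 1) * ci)
      mu[amp_S] <- b * fold_shared
    } else if (st == "costim:mixed") {
      mu[amp_A] <- b * fA; mu[amp_B] <- b * fB; mu[amp_S] <- b * fold_shared
    }
    mu
  }
  states <- unique(state)
  mu_by_state <- lapply(setNames(states, states), mu_for)
  if (any(!vapply(mu_by_state, function(m) all(is.finite(m) & m > 0), logical(1)))) {
    abort("Simulation means must be finite and positive.")
  }

  counts <- withr::with_seed(p$seed, {
    out <- matrix(0L, n_cells, p$n_genes)
    for (st in states) {
      idx <- which(state == st)
      mu <- mu_by_state[[st]]
      out[idx, ] <- rnbinom(length(idx) * p$n_genes,
                            mu = rep(mu, each = length(idx)),
                            size = p$dispersion)
    }
    out
  })
  dimnames(counts) <- list(cell_id, gene_id)

  fold_under <- function(stim) {
    ifelse(program == "shared", fold_shared,
           ifelse(program == stim, if (stim == "A") fA else fB, 1))
  }
  truth <- list(
    cells = tibble(cell_id = cell_id, condition = condition, state = state),
    genes = tibble(gene_id = gene_id, program = program,
                   fold_stimA = fold_under("A"), fold_stimB = fold_under("B")))
  list(counts = count_matrix(counts, condition), truth = truth)
}
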