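# Independent oracles used to pin expected values. Each is deliberately
# written with a different algorithm than the package implementation.

# Brute-force Benjamini-Hochberg step-up: for each p_i, the adjusted value
# is the minimum over all p_j >= p_i of n * p_j / rank(p_j), capped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  r <- vapply(p, function(x) sum(p <= x), numeric(1))
  vapply(seq_len(n), function(i) {
    cand <- vapply(which(p >= p[i]), function(j) n * p[j] / r[j], numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

# Exhaustive Fisher two-sided p for a 2x2 table by enumerating every table
# with the observed margins, probabilities from log-factorials (no dhyper).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0) return(1)
  xs <- max(0, k - n):min(k, m)
  logp <- vapply(xs, function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }, numeric(1))
  pr <- exp(logp)
  sum(pr[pr <= pr[xs == a] * (1 + 1e-7)])
}

# Spearman rho by explicit rank-then-Pearson sum formulas.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Small reference count simulation shared across tests.
small_sim <- function(seed = 11, n = 150, ci = 0.2,
                      fractions = c(0.45, 0.45, 0.10)) {
  simulate_counts(count_sim_params(
    n_cells_per_condition = n, n_genes = 150,
    n_program_genes_A = 25, n_program_genes_B = 25, n_shared_genes = 10,
    cross_inhibition = ci, costim_fractions = fractions, seed = seed))
}

# Chip already normalized in silico: pure zero-mean noise plus optional
# planted signal; used where a test needs a known normalized scale.
prenormalized_chip <- function(values, cell_count, analyte = "X") {
  wells <- tibble::tibble(
    well_id = sprintf("w%05d", seq_along(values)),
    row = 1L, col = seq_along(values), cell_count = cell_count)
  wells[[analyte]] <- values
  chip <- secretion_chip(wells, analyte)
  attr(chip, "stage") <- "normalized"
  chip
}
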