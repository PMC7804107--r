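# Internal numerical helpers shared across modules.

# Two-sided Fisher exact p-value for 2x2 tables, vectorized over tables.
# The two-sided p sums the probabilities of all tables (with the observed
# margins) whose probability does not exceed that of the observed table,
# with the customary (1 + 1e-7) relative guard against ties lost to
# floating point.
fisher_p_two_sided <- function(n11, n10, n01, n00) {
  stopifnot(length(n11) == length(n10), length(n10) == length(n01),
            length(n01) == length(n00))
  vapply(seq_along(n11), function(i) {
    a <- n11[i]; b <- n10[i]; c <- n01[i]; d <- n00[i]
    m <- a + b            # margin: feature A positive
    n <- c + d
    k <- a + c            # margin: feature B positive
    if (m + n == 0L) return(1)
    x <- max(0L, k - n):min(k, m)
    dens <- dhyper(x, m, n, k)
    sum(dens[dens <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }, numeric(1))
}

# Mann-Whitney/Wilcoxon rank-sum z-test applied column-wise to a matrix.
# Normal approximation with tie correction and continuity correction
# (matches wilcox.test(exact = FALSE, correct = TRUE)).
# `x` is a numeric matrix (units x features); `in_test` a logical vector
# over rows. Returns a vector of two-sided p-values per column.
ranksum_p <- function(x, in_test) {
  n1 <- sum(in_test)
  n2 <- sum(!in_test)
  stopifnot(n1 >= 2L, n2 >= 2L)
  nn <- n1 + n2
  apply(x, 2L, function(v) {
    r <- rank(v)
    w <- sum(r[in_test]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- (n1 * n2 / 12) * ((nn + 1) - tie_term / (nn * (nn - 1)))
    if (sigma2 <= 0) return(1)
    z <- w - n1 * n2 / 2
    z <- sign(z) * max(0, abs(z) - 0.5)   # continuity correction
    2 * pnorm(-abs(z) / sqrt(sigma2))
  })
}

# Dense matrix view of a (possibly sparse) cells x genes matrix subset.
dense_block <- function(m, rows = NULL, cols = NULL) {
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  if (!is.null(cols)) m <- m[, cols, drop = FALSE]
  as.matrix(m)
}

# Population variance (divides by n, not n - 1).
pop_var <- function(v) {
  mean((v - mean(v))^2)
}

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}
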