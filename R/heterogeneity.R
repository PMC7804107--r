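#' Significance-masked Spearman co-expression network
#'
#' Pairwise Spearman correlations between genes across single cells, with
#' coefficients whose p-value exceeds `p_mask` set to 0. P-values use the
#' t approximation for Spearman's rho on tie-corrected (mid) ranks.
#' Constant genes (zero rank variance) get rho 0 and p 1 for all their
#' pairs and are flagged.
#'
#' @param norm A `normalized_matrix`.
#' @param genes Genes to correlate (>= 2, present in the matrix).
#' @param condition Optional condition label(s) selecting cells; `NULL`
#'   uses all cells. At least 3 cells must remain.
#' @param p_mask Masking level (default 0.05).
#' @return A `masked_correlation` object: `genes`, `rho`, `p`,
#'   `rho_masked` (rho with p > `p_mask` zeroed), `constant` (logical per
#'   gene). `tidy()` returns the long pair table.
#' @export
spearman_network <- function(norm, genes, condition = NULL, p_mask = 0.05) {
  stopifnot(inherits(norm, "normalized_matrix"))
  missing_genes <- setdiff(genes, colnames(norm$values))
  if (length(missing_genes)) {
    abort(sprintf("Genes not present: %s",
                  paste(head(missing_genes, 5), collapse = ", ")))
  }
  rows <- if (is.null(condition)) seq_along(norm$condition) else
    which(norm$condition %in% condition)
  if (length(rows) < 3L) abort("Need at least 3 cells for correlation.")
  vals <- dense_block(norm$values, rows = rows, cols = genes)
  n <- nrow(vals)
  ranks <- apply(vals, 2L, rank)
  constant <- apply(ranks, 2L, function(r) stats::sd(r) == 0)
  rho <- suppressWarnings(stats::cor(ranks))        # Pearson on ranks
  rho[constant, ] <- 0
  rho[, constant] <- 0
  tt <- rho * sqrt(pmax(n - 2, 1) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  p[constant, ] <- 1
  p[, constant] <- 1
  diag(rho) <- 1
  diag(p) <- 0
  p <- pmin(p, 1)
  rho_masked <- rho * (p <= p_mask)
  structure(list(genes = genes, rho = rho, p = p, rho_masked = rho_masked,
                 constant = setNames(constant, genes), p_mask = p_mask,
                 n_cells = n),
            class = "masked_correlation")
}

#' @export
print.masked_correlation <- function(x, ...) {
  off <- upper.tri(x$p)
  cat(sprintf("<masked_correlation> %d genes, %d cells; %.1f%% of pairs masked (p > %.2f)\n",
              length(x$genes), x$n_cells,
              100 * mean(x$p[off] > x$p_mask), x$p_mask))
  invisible(x)
}

#' @method tidy masked_correlation
#' @export
tidy.masked_correlation <- function(x, ...) {
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble(gene_i = x$genes[idx[, 1]], gene_j = x$genes[idx[, 2]],
         rho = x$rho[idx], p = x$p[idx], rho_masked = x$rho_masked[idx])
}

#' Fano-factor noise table per gene and condition
#'
#' Computes mean, population variance and Fano factor (variance/mean) of
#' size-factor-scaled linear counts per gene within each condition. For
#' unique core genes, `delta_fano` is the co-stimulated Fano minus the
#' Fano under the gene's own single stimulus.
#'
#' @param counts A [count_matrix()].
#' @param size_factors Per-cell size factors (e.g. from
#'   [normalize_counts()]); `NULL` for raw counts.
#' @param program Optional [derive_program_sets()] result; when supplied,
#'   the `delta` table covers its UCGs.
#' @param costim_condition,stimA_condition,stimB_condition Condition labels.
#' @return A `noise_table`: `per_condition` tibble (gene, condition, mean,
#'   variance, fano, defined) and, when `program` is given, `delta` tibble
#'   (gene, program, fano_single, fano_costim, delta_fano). `tidy()`
#'   returns `per_condition`.
#' @export
fano_table <- function(counts, size_factors = NULL, program = NULL,
                       costim_condition = "costim",
                       stimA_condition = "stimA",
                       stimB_condition = "stimB") {
  stopifnot(inherits(counts, "count_matrix"))
  scaled <- as.matrix(counts$counts)
  if (!is.null(size_factors)) {
    sf <- size_factors[rownames(scaled)]
    if (anyNA(sf)) abort("Size factors missing for some cells.")
    scaled <- scaled / sf
  }
  per_condition <- purrr::map_dfr(unique(counts$condition), function(cond) {
    block <- scaled[counts$condition == cond, , drop = FALSE]
    m <- unname(colMeans(block))
    v <- unname(colMeans(block^2)) - m^2  # population variance
    tibble(gene = colnames(block), condition = cond, mean = m,
           variance = pmax(v, 0), fano = ifelse(m > 0, pmax(v, 0) / m, NA_real_),
           defined = m > 0)
  })
  delta <- NULL
  if (!is.null(program)) {
    stopifnot(inherits(program, "program_sets"))
    fano_of <- function(gene, cond) {
      per_condition$fano[per_condition$gene == gene &
                           per_condition$condition == cond]
    }
    ucg <- tibble(gene = c(program$ucg_A, program$ucg_B),
                  program = rep(c("A", "B"),
                                c(length(program$ucg_A), length(program$ucg_B))))
    wide <- tidyr::pivot_wider(per_condition[, c("gene", "condition", "fano")],
                               names_from = "condition", values_from = "fano")
    delta <- ucg |>
      left_join(wide, by = "gene") |>
      mutate(fano_single = ifelse(.data$program == "A",
                                  .data[[stimA_condition]],
                                  .data[[stimB_condition]]),
             fano_costim = .data[[costim_condition]],
             delta_fano = .data$fano_costim - .data$fano_single) |>
      select("gene", "program", "fano_single", "fano_costim", "delta_fano")
  }
  structure(list(per_condition = per_condition, delta = delta),
            class = "noise_table")
}

#' @export
print.noise_table <- function(x, ...) {
  cat(sprintf("<noise_table> %d genes x %d conditions\n",
              length(unique(x$per_condition$gene)),
              length(unique(x$per_condition$condition))))
  if (!is.null(x$delta)) {
    cat(sprintf("  delta_fano available for %d UCGs\n", nrow(x$delta)))
  }
  invisible(x)
}

#' @method tidy noise_table
#' @export
tidy.noise_table <- function(x, ...) x$per_condition

#' Rank cross-inhibited genes by their gain in expression noise
#'
#' Orders the inhibited UCGs of each program by decreasing `delta_fano`
#' (co-stimulated Fano minus single-stimulus Fano). Ties keep input
#' order (stable sort). Genes with undefined Fano are excluded.
#'
#' @param noise A [fano_table()] result computed with a program.
#' @param program A [classify_cross_regulation()] result providing
#'   inhibited/augmented labels.
#' @param top_k Report at most this many genes per program.
#' @return Tibble (program, gene, delta_fano, rank).
#' @export
rank_noise_shifts <- function(noise, program, top_k = Inf) {
  stopifnot(inherits(noise, "noise_table"), inherits(program, "program_sets"))
  if (is.null(noise$delta)) {
    abort("`noise` was computed without program sets; rerun `fano_table()` with `program`.")
  }
  inhibited <- program$cross_regulation$gene[
    program$cross_regulation$label == "inhibited"]
  d <- noise$delta[noise$delta$gene %in% inhibited &
                     !is.na(noise$delta$delta_fano), , drop = FALSE]
  if (!nrow(d)) {
    return(tibble(program = character(), gene = character(),
                  delta_fano = numeric(), rank = integer()))
  }
  d |>
    group_by(.data$program) |>
    arrange(desc(.data$delta_fano), .by_group = TRUE) |>
    mutate(rank = seq_len(dplyr::n())) |>
    ungroup() |>
    filter(.data$rank <= top_k) |>
    select("program", "gene", "delta_fano", "rank")
}

#' Per-cell program expression score
#'
#' The score of a cell for a gene set is the mean normalized value over
#' the set minus the mean over a background set of
#' `n_background * length(genes)` genes sampled uniformly (seeded,
#' without replacement when possible) from the non-member genes.
#' `n_background = 0` disables background correction (plain set mean).
#' Sampling is performed on the sorted gene universe, so scores are
#' invariant to the column order of the matrix.
#'
#' @param norm A `normalized_matrix`.
#' @param genes Gene set to score (non-empty).
#' @param n_background Background genes sampled per member gene.
#' @param seed Seed for background sampling.
#' @param condition Optional condition filter for the scored cells.
#' @return Tibble (cell_id, condition, score).
#' @export
ucg_score <- function(norm, genes, n_background = 50, seed = 1L,
                      condition = NULL) {
  stopifnot(inherits(norm, "normalized_matrix"))
  genes <- unique(as.character(genes))
  if (!length(genes)) abort("Gene set must be non-empty.")
  missing_genes <- setdiff(genes, colnames(norm$values))
  if (length(missing_genes)) {
    abort(sprintf("Genes not present: %s",
                  paste(head(missing_genes, 5), collapse = ", ")))
  }
  rows <- if (is.null(condition)) seq_along(norm$condition) else
    which(norm$condition %in% condition)
  vals <- norm$values[rows, , drop = FALSE]
  score <- Matrix::rowSums(vals[, genes, drop = FALSE]) / length(genes)
  if (n_background > 0) {
    pool <- sort(setdiff(colnames(norm$values), genes))
    if (!length(pool)) abort("No background genes available.")
    n_bg <- min(length(pool), n_background * length(genes))
    bg <- withr::with_seed(seed, sample(pool, n_bg))
    score <- score - Matrix::rowSums(vals[, bg, drop = FALSE]) / n_bg
  }
  tibble(cell_id = rownames(vals), condition = norm$condition[rows],
         score = as.numeric(score))
}

#' Paired program scores for co-stimulated cells
#'
#' Convenience wrapper computing [ucg_score()] for both UCG sets of a
#' program object on the same cells.
#'
#' @inheritParams ucg_score
#' @param program A [derive_program_sets()] result with non-empty UCG sets.
#' @return Tibble (cell_id, condition, score_A, score_B).
#' @export
ucg_score_pair <- function(norm, program, n_background = 50, seed = 1L,
                           condition = NULL) {
  stopifnot(inherits(program, "program_sets"))
  a <- ucg_score(norm, program$ucg_A, n_background, seed, condition)
  b <- ucg_score(norm, program$ucg_B, n_background, seed, condition)
  tibble(cell_id = a$cell_id, condition = a$condition,
         score_A = a$score, score_B = b$score)
}

#' Write the long-format correlation table to TSV
#' @param x A `masked_correlation`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_correlation_tsv <- function(x, file) {
  write.table(as.data.frame(tidy(x)), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
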