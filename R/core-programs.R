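#' Quality-control filtering of cells and genes
#'
#' Removes cells whose number of detected genes (count >= 1) falls outside
#' `[min_genes_per_cell, max_genes_per_cell]`, then genes detected in fewer
#' than `min_cells_per_gene` of the remaining cells. Intended to remove
#' dead/empty cells (few genes) and likely doublets (too many genes).
#'
#' @param x A [count_matrix()].
#' @param min_genes_per_cell,max_genes_per_cell Detected-gene bounds per
#'   cell. `max_genes_per_cell = NULL` uses twice the median detected-gene
#'   count, a conventional doublet guard.
#' @param min_cells_per_gene Minimum number of cells a gene must be
#'   detected in.
#' @return A filtered [count_matrix()] with original ordering preserved.
#' @export
qc_filter <- function(x, min_genes_per_cell = 200, max_genes_per_cell = NULL,
                      min_cells_per_gene = 3) {
  stopifnot(inherits(x, "count_matrix"))
  detected <- Matrix::rowSums(x$counts > 0)
  if (is.null(max_genes_per_cell)) max_genes_per_cell <- 2 * median(detected)
  if (min_genes_per_cell < 0 || min_cells_per_gene < 0) {
    abort("QC thresholds must be non-negative.")
  }
  if (min_genes_per_cell >= max_genes_per_cell) {
    abort("`min_genes_per_cell` must be below `max_genes_per_cell`.")
  }
  keep_cells <- detected >= min_genes_per_cell & detected <= max_genes_per_cell
  if (!any(keep_cells)) abort("All cells filtered out by QC thresholds.")
  counts <- x$counts[keep_cells, , drop = FALSE]
  keep_genes <- Matrix::colSums(counts > 0) >= min_cells_per_gene
  if (!any(keep_genes)) abort("All genes filtered out by QC thresholds.")
  count_matrix(counts[, keep_genes, drop = FALSE],
               x$condition[keep_cells])
}

#' Library-size normalization with log transform
#'
#' Size factors are per-cell total counts rescaled so that their median is
#' exactly 1; normalized values are `ln(count / size_factor + 1)`.
#' Multiplying every cell's counts by the same constant leaves the values
#' invariant.
#'
#' @param x A [count_matrix()] with no zero-total cells.
#' @return A `normalized_matrix`: list with `values` (sparse cells x genes
#'   matrix of `ln(count/sf + 1)`), `size_factors` (named, median 1) and
#'   `condition`.
#' @export
normalize_counts <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  totals <- Matrix::rowSums(x$counts)
  if (any(totals == 0)) {
    bad <- names(totals)[totals == 0]
    abort(sprintf("Cells with zero total counts cannot be normalized: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  sf <- totals / median(totals)
  # ln(count/sf + 1) preserves sparsity: zeros map to zero.
  values <- Matrix::Diagonal(x = 1 / sf) %*% x$counts
  values@x <- log1p(values@x)
  values <- methods::as(methods::as(values, "CsparseMatrix"), "generalMatrix")
  dimnames(values) <- dimnames(x$counts)
  structure(list(values = values, size_factors = setNames(sf, rownames(x$counts)),
                 condition = x$condition),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d cells x %d genes, ln(count/sf + 1)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Per-gene Wilcoxon rank-sum differential expression
#'
#' Two-sided rank-sum test on normalized values per gene between two
#' conditions, Benjamini-Hochberg correction across all tested genes.
#' Fold change is computed on de-logged normalized means,
#' `(mean(expm1(test)) + eps) / (mean(expm1(ref)) + eps)` with
#' `eps = 1e-9`. The rank-sum p uses the normal approximation with tie and
#' continuity corrections. A gene is called `up` when
#' `fold_change >= fc_threshold` and `fdr <= fdr_max`, `down` when
#' `1/fold_change >= fc_threshold` and `fdr <= fdr_max`, otherwise `ns`.
#'
#' @param norm A `normalized_matrix` from [normalize_counts()].
#' @param test_condition,ref_condition Condition labels to compare; both
#'   must have at least 2 cells.
#' @param fc_threshold,fdr_max Call thresholds used for `direction`.
#' @return A tibble with one row per gene: `gene`, `fold_change`,
#'   `p_value`, `fdr`, `frac_expressed_test`, `frac_expressed_ref`,
#'   `direction`. Conditions are recorded in attributes `test_condition`
#'   and `ref_condition`.
#' @export
differential_expression <- function(norm, test_condition, ref_condition,
                                    fc_threshold = 1.5, fdr_max = 0.05) {
  stopifnot(inherits(norm, "normalized_matrix"))
  for (cond in c(test_condition, ref_condition)) {
    if (!cond %in% norm$condition) {
      abort(sprintf("Unknown condition label: '%s'.", cond))
    }
  }
  sel <- norm$condition %in% c(test_condition, ref_condition)
  vals <- dense_block(norm$values, rows = which(sel))
  in_test <- norm$condition[sel] == test_condition
  if (sum(in_test) < 2L || sum(!in_test) < 2L) {
    abort("Both conditions need at least 2 cells.")
  }
  p <- ranksum_p(vals, in_test)
  fdr <- p.adjust(p, method = "BH")
  eps <- 1e-9
  mean_test <- colMeans(expm1(vals[in_test, , drop = FALSE]))
  mean_ref <- colMeans(expm1(vals[!in_test, , drop = FALSE]))
  fc <- (mean_test + eps) / (mean_ref + eps)
  frac_test <- colMeans(vals[in_test, , drop = FALSE] > 0)
  frac_ref <- colMeans(vals[!in_test, , drop = FALSE] > 0)
  direction <- dplyr::case_when(
    fc >= fc_threshold & fdr <= fdr_max ~ "up",
    1 / fc >= fc_threshold & fdr <= fdr_max ~ "down",
    TRUE ~ "ns")
  out <- tibble(gene = colnames(vals), fold_change = fc, p_value = p,
                fdr = fdr, frac_expressed_test = frac_test,
                frac_expressed_ref = frac_ref, direction = direction)
  attr(out, "test_condition") <- test_condition
  attr(out, "ref_condition") <- ref_condition
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "fdr_max") <- fdr_max
  class(out) <- c("de_result", class(out))
  out
}

#' Core genes of a stimulation program
#'
#' A core gene is upregulated versus control with fold change at least
#' `fc_min`, FDR at most `fdr_max`, and detected (count >= 1) in at least
#' `frac_min` of the stimulated cells.
#'
#' @param de A [differential_expression()] result computed stimulus vs
#'   control.
#' @param fc_min,fdr_max,frac_min Selection thresholds (defaults 1.5,
#'   0.05, 0.15).
#' @return Character vector of core gene ids.
#' @export
define_core_genes <- function(de, fc_min = 1.5, fdr_max = 0.05,
                              frac_min = 0.15) {
  stopifnot(is.data.frame(de))
  de$gene[de$fold_change >= fc_min & de$fdr <= fdr_max &
            de$frac_expressed_test >= frac_min]
}

#' Program sets: unique and shared core genes
#'
#' @param core_A,core_B Character vectors of core genes for the two
#'   stimuli (same gene universe).
#' @return A `program_sets` object with `core_A`, `core_B`,
#'   `shared = core_A intersect core_B`, `ucg_A = core_A \\ core_B`,
#'   `ucg_B = core_B \\ core_A`, and an (initially empty)
#'   `cross_regulation` tibble.
#' @export
derive_program_sets <- function(core_A, core_B) {
  core_A <- unique(as.character(core_A))
  core_B <- unique(as.character(core_B))
  structure(list(core_A = core_A, core_B = core_B,
                 shared = intersect(core_A, core_B),
                 ucg_A = setdiff(core_A, core_B),
                 ucg_B = setdiff(core_B, core_A),
                 cross_regulation = tibble(gene = character(),
                                           program = character(),
                                           label = character())),
            class = "program_sets")
}

#' @export
print.program_sets <- function(x, ...) {
  cat(sprintf("<program_sets> core A: %d, core B: %d, shared: %d, UCG A: %d, UCG B: %d\n",
              length(x$core_A), length(x$core_B), length(x$shared),
              length(x$ucg_A), length(x$ucg_B)))
  if (nrow(x$cross_regulation)) {
    print(dplyr::count(x$cross_regulation, .data$program, .data$label))
  }
  invisible(x)
}

#' Cross-regulation of unique core genes under co-stimulation
#'
#' For each unique core gene (UCG) of a program, compares co-stimulated
#' cells with cells receiving that program's stimulus alone. A UCG is
#' `inhibited` when significantly down (FDR <= `fdr_max`, fold change
#' >= `fc_min` in the downward direction), `augmented` when significantly
#' up, otherwise `unchanged`.
#'
#' @param norm A `normalized_matrix` containing `costim` and the
#'   single-stimulus conditions.
#' @param program A [derive_program_sets()] result.
#' @param fc_min,fdr_max Call thresholds.
#' @param costim_condition,stimA_condition,stimB_condition Condition
#'   labels.
#' @return `program` with the `cross_regulation` tibble filled
#'   (`gene`, `program`, `label`, `fold_change`, `fdr`).
#' @export
classify_cross_regulation <- function(norm, program, fc_min = 1.5,
                                      fdr_max = 0.05,
                                      costim_condition = "costim",
                                      stimA_condition = "stimA",
                                      stimB_condition = "stimB") {
  stopifnot(inherits(norm, "normalized_matrix"),
            inherits(program, "program_sets"))
  if (!costim_condition %in% norm$condition) {
    abort("Co-stimulated condition is missing from the data.")
  }
  one_side <- function(ucg, stim_condition, prog_label) {
    if (!length(ucg)) {
      return(tibble(gene = character(), program = character(),
                    label = character(), fold_change = numeric(),
                    fdr = numeric()))
    }
    de <- differential_expression(norm, costim_condition, stim_condition,
                                  fc_threshold = fc_min, fdr_max = fdr_max)
    de <- de[match(ucg, de$gene), ]
    tibble(gene = ucg, program = prog_label,
           label = dplyr::case_when(de$direction == "down" ~ "inhibited",
                                    de$direction == "up" ~ "augmented",
                                    TRUE ~ "unchanged"),
           fold_change = de$fold_change, fdr = de$fdr)
  }
  program$cross_regulation <- bind_rows(
    one_side(program$ucg_A, stimA_condition, "A"),
    one_side(program$ucg_B, stimB_condition, "B"))
  program
}

#' Genes of a program showing cross-inhibition
#' @param program A [classify_cross_regulation()] result.
#' @return Character vector of inhibited UCGs (both programs).
#' @export
cross_inhibited_ucgs <- function(program) {
  stopifnot(inherits(program, "program_sets"))
  cr <- program$cross_regulation
  if (!nrow(cr)) {
    abort("Cross-regulation labels are empty; run `classify_cross_regulation()` first.")
  }
  cr$gene[cr$label == "inhibited"]
}

#' Write a differential-expression table or program sets to TSV
#' @param x Object to write.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_de_tsv <- function(x, file) {
  write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname write_de_tsv
#' @export
write_program_sets_tsv <- function(x, file) {
  stopifnot(inherits(x, "program_sets"))
  sets <- tibble(
    gene = c(x$ucg_A, x$ucg_B, x$shared),
    set = rep(c("ucg_A", "ucg_B", "shared"),
              c(length(x$ucg_A), length(x$ucg_B), length(x$shared))))
  out <- left_join(sets, x$cross_regulation[, c("gene", "label")], by = "gene")
  write.table(as.data.frame(out), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
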