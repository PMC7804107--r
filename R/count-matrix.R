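#' UMI count matrix with per-cell condition labels
#'
#' The basic substrate for the scRNA-seq stages: a cells x genes matrix of
#' non-negative integer UMI counts together with one condition label per
#' cell. Conditions are free-form strings, but the canonical design uses
#' `"control"`, `"stimA"` (inflammatory cue), `"stimB"` (resolving cue) and
#' `"costim"` (both cues at once).
#'
#' @param counts A cells x genes matrix (base or `Matrix` sparse) of
#'   non-negative integers. Row names are cell ids, column names gene ids;
#'   defaults are generated when absent.
#' @param condition Character vector of condition labels, one per cell
#'   (recycled if length 1).
#' @return A `count_matrix` object: a list with elements `counts` (a
#'   `dgCMatrix`, cells x rows) and `condition` (named character vector).
#' @examples
#' m <- matrix(rpois(12, 1), nrow = 3,
#'             dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
#' cm <- count_matrix(m, c("control", "stimA", "stimB"))
#' dim(cm)
#' @export
count_matrix <- function(counts, condition) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0)) abort("Counts must be non-negative.")
  if (any(counts@x != round(counts@x))) abort("Counts must be integers.")
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("cell%0*d", nchar(nrow(counts)), seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("gene%0*d", nchar(ncol(counts)), seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) abort("Cell ids must be unique.")
  if (anyDuplicated(colnames(counts))) abort("Gene ids must be unique.")
  if (length(condition) == 1L) condition <- rep(condition, nrow(counts))
  if (length(condition) != nrow(counts)) {
    abort("`condition` must supply exactly one label per cell.")
  }
  condition <- as.character(condition)
  if (anyNA(condition)) abort("Condition labels must not be NA.")
  names(condition) <- rownames(counts)
  structure(list(counts = counts, condition = condition),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  tab <- table(x$condition)
  cat(sprintf("<count_matrix> %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  conditions:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Cell ids, gene ids and condition labels of a count matrix
#' @param x A `count_matrix` or `normalized_matrix`.
#' @return Character vector.
#' @export
cell_ids <- function(x) rownames(x$counts %||% x$values)

#' @rdname cell_ids
#' @export
gene_ids <- function(x) colnames(x$counts %||% x$values)

#' @rdname cell_ids
#' @export
conditions <- function(x) x$condition

#' Read a 10x-style MTX triple into a count matrix
#'
#' Expects `matrix.mtx` (MatrixMarket, genes x cells or cells x genes; the
#' orientation is inferred from the barcode/feature list lengths),
#' `barcodes.tsv` and `features.tsv` in `dir`, plus a two-column
#' conditions TSV (`cell_id`, `condition`).
#'
#' @param dir Directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`.
#' @param conditions_file Path to a two-column TSV mapping cell id to
#'   condition; if `NULL`, all cells are labelled `"unknown"`.
#' @return A [count_matrix()].
#' @export
read_counts_mtx <- function(dir, conditions_file = NULL) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  features <- read.delim(file.path(dir, "features.tsv"), header = FALSE)[[1]]
  if (nrow(m) == length(features) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)  # 10x convention: genes x cells on disk
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(features))) {
    abort("MTX dimensions do not match barcode/feature list lengths.")
  }
  rownames(m) <- barcodes
  colnames(m) <- features
  cond <- rep("unknown", length(barcodes))
  if (!is.null(conditions_file)) {
    tab <- read.delim(conditions_file, header = TRUE,
                      col.names = c("cell_id", "condition"))
    cond <- tab$condition[match(barcodes, tab$cell_id)]
    if (anyNA(cond)) abort("Conditions file is missing some barcodes.")
  }
  count_matrix(m, cond)
}

#' @rdname read_counts_mtx
#' @param file Dense TSV with cell ids in the first column and one column
#'   per gene.
#' @export
read_counts_tsv <- function(file, conditions_file = NULL) {
  tab <- read.delim(file, header = TRUE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  cond <- rep("unknown", nrow(m))
  if (!is.null(conditions_file)) {
    ct <- read.delim(conditions_file, header = TRUE,
                     col.names = c("cell_id", "condition"))
    cond <- ct$condition[match(rownames(m), ct$cell_id)]
    if (anyNA(cond)) abort("Conditions file is missing some cells.")
  }
  count_matrix(m, cond)
}

#' Write a count matrix as an MTX triple plus conditions TSV
#'
#' @param x A [count_matrix()].
#' @param dir Output directory (created if needed). Writes `matrix.mtx`
#'   (genes x cells, 10x orientation), `barcodes.tsv`, `features.tsv` and
#'   `conditions.tsv`.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(x$counts), file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "features.tsv"))
  write.table(
    data.frame(cell_id = names(x$condition), condition = x$condition),
    file.path(dir, "conditions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
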