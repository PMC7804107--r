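#' Binarize expression or secretion values
#'
#' Converts a matrix of values to positive/negative calls against a
#' per-feature threshold. For RNA counts the convention is inclusive
#' (positive iff count >= threshold; the canonical choice is 2 detected
#' transcripts). Secretion calls use a strict comparison (see
#' [secretion_calls()]), controlled here by `inclusive`.
#'
#' @param x A [count_matrix()], or a numeric matrix (units x features).
#' @param threshold Scalar or per-feature named vector of thresholds.
#' @param condition Optional condition filter (count matrices only).
#' @param inclusive Positive iff `value >= threshold` (`TRUE`, RNA
#'   default) or `value > threshold` (`FALSE`).
#' @param provenance `"rna"` or `"secretion"`; recorded on the result.
#' @return A `binary_matrix`: list with `positive` (logical units x
#'   features), `thresholds` (named per feature), `provenance`.
#' @export
binarize <- function(x, threshold = 2, condition = NULL, inclusive = TRUE,
                     provenance = "rna") {
  UseMethod("binarize")
}

#' @export
binarize.count_matrix <- function(x, threshold = 2, condition = NULL,
                                  inclusive = TRUE, provenance = "rna") {
  rows <- if (is.null(condition)) seq_along(x$condition) else
    which(x$condition %in% condition)
  binarize(dense_block(x$counts, rows = rows), threshold = threshold,
           inclusive = inclusive, provenance = provenance)
}

#' @export
binarize.matrix <- function(x, threshold = 2, condition = NULL,
                            inclusive = TRUE, provenance = "rna") {
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  thr <- if (length(threshold) == 1L) {
    setNames(rep(as.numeric(threshold), ncol(x)), colnames(x))
  } else {
    if (is.null(names(threshold))) {
      stopifnot(length(threshold) == ncol(x))
      setNames(as.numeric(threshold), colnames(x))
    } else {
      missing_f <- setdiff(colnames(x), names(threshold))
      if (length(missing_f)) {
        abort(sprintf("No threshold for features: %s",
                      paste(head(missing_f, 5), collapse = ", ")))
      }
      threshold[colnames(x)]
    }
  }
  if (any(!is.finite(thr))) abort("Thresholds must be finite.")
  pos <- if (inclusive) sweep(x, 2L, thr, `>=`) else sweep(x, 2L, thr, `>`)
  structure(list(positive = pos, thresholds = thr, provenance = provenance),
            class = "binary_matrix")
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat(sprintf("<binary_matrix> %d units x %d features (%s); %.1f%% positive\n",
              nrow(x$positive), ncol(x$positive), x$provenance,
              100 * mean(x$positive)))
  invisible(x)
}

#' Significance-masked pairwise log2 odds ratios
#'
#' For every feature pair, builds the 2x2 joint positive/negative table
#' and computes the odds ratio `(n11 * n00) / (n10 * n01)`. When any cell
#' of the table is zero, 0.5 is added to all four cells before taking the
#' ratio (Haldane-Anscombe; flagged per pair). The two-sided Fisher exact
#' p-value is always computed on the uncorrected table. Entries with
#' `p > p_mask` are set to 0 in `log2_or_masked`. A negative masked log2
#' odds ratio means the two features are expressed mutually exclusively
#' ("orthogonally").
#'
#' @param bin A [binarize()] result.
#' @param features Optional feature subset (default: all).
#' @param p_mask Masking level (default 0.05).
#' @return An `odds_ratio_result`: `features`, matrices `log2_or`, `p`,
#'   `log2_or_masked`, `correction_applied`, and `pairs`, a long tibble
#'   with the 2x2 counts per pair. `tidy()` returns `pairs`.
#' @export
pairwise_odds_ratios <- function(bin, features = NULL, p_mask = 0.05) {
  stopifnot(inherits(bin, "binary_matrix"))
  pos <- bin$positive
  if (!is.null(features)) {
    missing_f <- setdiff(features, colnames(pos))
    if (length(missing_f)) {
      abort(sprintf("Features not present: %s",
                    paste(head(missing_f, 5), collapse = ", ")))
    }
    pos <- pos[, features, drop = FALSE]
  }
  if (ncol(pos) < 2L) abort("Need at least 2 features.")
  if (nrow(pos) < 1L) abort("Need at least 1 unit.")
  storage.mode(pos) <- "double"
  n <- nrow(pos)
  n11 <- crossprod(pos)                      # both positive
  ci <- matrix(colSums(pos), ncol(pos), ncol(pos))  # ci[i, j] = positives of i
  n10 <- ci - n11                            # i positive only
  n01 <- t(ci) - n11                         # j positive only
  n00 <- n - n11 - n10 - n01
  idx <- which(upper.tri(n11), arr.ind = TRUE)
  a <- n11[idx]; b <- n10[idx]; c0 <- n01[idx]; d <- n00[idx]
  corrected <- a == 0 | b == 0 | c0 == 0 | d == 0
  or <- ifelse(corrected,
               ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c0 + 0.5)),
               (a * d) / (b * c0))
  p_vec <- fisher_p_two_sided(a, b, c0, d)
  feat <- colnames(pos)
  k <- length(feat)
  mk <- function(v, diag_val) {
    m <- matrix(diag_val, k, k, dimnames = list(feat, feat))
    m[upper.tri(m)] <- v
    m[lower.tri(m)] <- Matrix::t(m)[lower.tri(m)]
    m
  }
  log2_or <- mk(log2(or), 0)
  p <- mk(p_vec, 0)
  correction_applied <- mk(corrected, FALSE)
  log2_or_masked <- log2_or * (p <= p_mask)
  pairs <- tibble(feature_i = feat[idx[, 1]], feature_j = feat[idx[, 2]],
                  n11 = a, n10 = b, n01 = c0, n00 = d,
                  or = or, log2_or = log2(or), p = p_vec,
                  log2_or_masked = log2_or_masked[idx],
                  corrected = corrected)
  structure(list(features = feat, log2_or = log2_or, p = p,
                 log2_or_masked = log2_or_masked,
                 correction_applied = correction_applied,
                 pairs = pairs, n_units = n, p_mask = p_mask,
                 provenance = bin$provenance),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("<odds_ratio_result> %d features, %d units (%s)\n",
              length(x$features), x$n_units, x$provenance))
  cat(sprintf("  %d / %d pairs survive the p <= %.2f mask; %d negative\n",
              sum(x$pairs$p <= x$p_mask), nrow(x$pairs), x$p_mask,
              sum(x$pairs$log2_or_masked < 0)))
  invisible(x)
}

#' @method tidy odds_ratio_result
#' @export
tidy.odds_ratio_result <- function(x, ...) x$pairs

#' Mutually exclusive ("orthogonal") feature pairs
#'
#' Reports pairs with a negative masked log2 odds ratio, annotated as
#' within-program or cross-program using core program membership.
#'
#' @param or_result A [pairwise_odds_ratios()] result.
#' @param program Optional [derive_program_sets()] result for the
#'   within/cross-program annotation; features in `core_A` only count as
#'   side A, `core_B` only as side B.
#' @return Tibble of negative pairs (feature_i, feature_j, log2_or, p,
#'   class) with a `summary` attribute counting pairs per class.
#' @export
orthogonal_pairs <- function(or_result, program = NULL) {
  stopifnot(inherits(or_result, "odds_ratio_result"))
  neg <- or_result$pairs |>
    filter(.data$log2_or_masked < 0) |>
    select("feature_i", "feature_j", "log2_or", "p")
  side <- function(f) {
    if (is.null(program)) return(rep(NA_character_, length(f)))
    dplyr::case_when(f %in% program$ucg_A ~ "A",
                     f %in% program$ucg_B ~ "B",
                     f %in% program$shared ~ "shared",
                     TRUE ~ NA_character_)
  }
  neg <- neg |>
    mutate(side_i = side(.data$feature_i), side_j = side(.data$feature_j),
           class = dplyr::case_when(
             is.na(.data$side_i) | is.na(.data$side_j) ~ "unannotated",
             .data$side_i == .data$side_j ~ "within_program",
             .data$side_i != .data$side_j &
               .data$side_i %in% c("A", "B") &
               .data$side_j %in% c("A", "B") ~ "cross_program",
             TRUE ~ "shared_involved")) |>
    select(-"side_i", -"side_j")
  attr(neg, "summary") <- dplyr::count(neg, .data$class, name = "n_pairs")
  neg
}

#' Percent reduction in odds implied by an odds ratio
#'
#' A ratio below 1 means the odds of one feature are reduced in the
#' presence of the other; e.g. an odds ratio of 0.44 is a 56% reduction.
#'
#' @param or Odds ratio(s).
#' @return Percent reduction, `100 * (1 - or)`.
#' @export
odds_reduction_percent <- function(or) 100 * (1 - or)

#' Write the long-format odds-ratio table to TSV
#' @param x An `odds_ratio_result`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_odds_ratios_tsv <- function(x, file) {
  write.table(as.data.frame(tidy(x)), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
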