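#' Microwell secretion chip container
#'
#' One row per well with its array coordinates, live-cell count and raw
#' fluorescence intensity (a.f.u.) per analyte. Zero-cell wells
#' (`cell_count == 0`) double as the background model for normalization
#' and thresholding.
#'
#' @param wells Data frame with columns `well_id`, `row`, `col`,
#'   `cell_count`, plus one numeric column per analyte.
#' @param analytes Analyte column names; defaults to every column after
#'   the four well columns.
#' @return A `secretion_chip` tibble with attributes `analytes` and
#'   `stage` (`"raw"`).
#' @export
secretion_chip <- function(wells, analytes = NULL) {
  wells <- as_tibble(wells)
  needed <- c("well_id", "row", "col", "cell_count")
  if (!all(needed %in% names(wells))) {
    abort("Chip table needs columns well_id, row, col, cell_count.")
  }
  if (is.null(analytes)) analytes <- setdiff(names(wells), needed)
  if (!length(analytes)) abort("Chip has no analyte columns.")
  if (anyDuplicated(wells$well_id)) abort("Well ids must be unique.")
  for (a in analytes) {
    if (!is.numeric(wells[[a]]) || any(!is.finite(wells[[a]]))) {
      abort(sprintf("Analyte '%s' must be finite numeric.", a))
    }
  }
  if (any(wells$cell_count < 0)) abort("Cell counts must be >= 0.")
  structure(wells, analytes = analytes, stage = "raw",
            class = c("secretion_chip", class(wells)))
}

#' @export
print.secretion_chip <- function(x, ...) {
  cat(sprintf("<secretion_chip:%s> %d wells (%d zero-cell, %d single-cell), analytes: %s\n",
              attr(x, "stage"), nrow(x), sum(x$cell_count == 0),
              sum(x$cell_count == 1),
              paste(attr(x, "analytes"), collapse = ", ")))
  NextMethod()
}

#' Read / write a secretion chip TSV
#' @param file TSV with columns well_id, row, col, cell_count and one
#'   column per analyte.
#' @return A [secretion_chip()].
#' @export
read_chip_tsv <- function(file) {
  secretion_chip(read.delim(file, header = TRUE, check.names = FALSE))
}

#' @rdname read_chip_tsv
#' @param chip A `secretion_chip`.
#' @export
write_chip_tsv <- function(chip, file) {
  write.table(as.data.frame(chip), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

# Row-major array index of each well.
array_index <- function(chip) {
  (chip$row - min(chip$row)) * (max(chip$col) - min(chip$col) + 1L) +
    (chip$col - min(chip$col)) + 1L
}

#' Local zero-cell background normalization
#'
#' For each well the `window` nearest zero-cell wells in row-major array
#' order define the local background; a Gaussian is fitted to their
#' intensities (location = mean, scale = SD) and the fitted location is
#' subtracted from the well's raw intensity, analyte by analyte.
#' Normalized zero-cell wells therefore center near 0, and smooth spatial
#' drift is removed up to its variation within the window.
#'
#' @param chip A raw [secretion_chip()].
#' @param window Number of nearest zero-cell wells in the moving fit
#'   (default 50).
#' @return The chip with analyte columns replaced by normalized
#'   intensities; `stage` becomes `"normalized"` and the window is
#'   recorded.
#' @export
background_normalize <- function(chip, window = 50L) {
  stopifnot(inherits(chip, "secretion_chip"))
  analytes <- attr(chip, "analytes")
  window <- as.integer(window)
  zero <- which(chip$cell_count == 0)
  if (length(zero) < window) {
    abort(sprintf("Need at least %d zero-cell wells for the moving fit; found %d.",
                  window, length(zero)))
  }
  idx <- array_index(chip)
  ord_zero <- zero[order(idx[zero])]
  zidx <- idx[ord_zero]
  zvals <- as.matrix(chip[ord_zero, analytes, drop = FALSE])
  K <- length(zidx)
  n_starts <- K - window + 1L
  # For each well, the `window` nearest zero wells (by array-index
  # distance) form a contiguous block; pick the block minimizing the
  # distance to the farther end.
  pos <- findInterval(idx, zidx)
  start <- pmin(pmax(pos - window %/% 2L, 1L), n_starts)
  # refine: slide the block while the excluded near end is closer than
  # the included far end
  refine <- function(i) {
    s <- start[i]
    repeat {
      moved <- FALSE
      if (s > 1L && abs(zidx[s - 1L] - idx[i]) < abs(zidx[s + window - 1L] - idx[i])) {
        s <- s - 1L; moved <- TRUE
      } else if (s < n_starts &&
                 abs(zidx[s + window] - idx[i]) < abs(zidx[s] - idx[i])) {
        s <- s + 1L; moved <- TRUE
      }
      if (!moved) break
    }
    as.integer(s)
  }
  start <- vapply(seq_along(idx), refine, integer(1))
  # block means per unique window start; mean() so a flat background
  # cancels exactly
  us <- unique(start)
  bg_by_start <- vapply(us, function(s) {
    apply(zvals[s:(s + window - 1L), , drop = FALSE], 2L, mean)
  }, numeric(length(analytes)))
  bg_by_start <- matrix(bg_by_start, nrow = length(us), byrow = TRUE)
  bg <- bg_by_start[match(start, us), , drop = FALSE]
  out <- chip
  for (j in seq_along(analytes)) {
    out[[analytes[j]]] <- chip[[analytes[j]]] - bg[, j]
  }
  attr(out, "stage") <- "normalized"
  attr(out, "window") <- as.integer(window)
  out
}

#' Per-analyte secretion thresholds from zero-cell wells
#'
#' The threshold for each analyte is the 99th percentile (linear
#' interpolation between order statistics, i.e. `quantile()` type 7) of
#' the normalized zero-cell well intensities. By construction at most 1%
#' of zero-cell wells exceed their threshold.
#'
#' @param chip A normalized [secretion_chip()].
#' @param probs Percentile used (default 0.99).
#' @return Tibble (analyte, threshold).
#' @export
compute_thresholds <- function(chip, probs = 0.99) {
  stopifnot(inherits(chip, "secretion_chip"))
  if (!identical(attr(chip, "stage"), "normalized")) {
    warn("Chip is not marked normalized; thresholds will include background.")
  }
  analytes <- attr(chip, "analytes")
  zero <- chip$cell_count == 0
  if (!any(zero)) abort("No zero-cell wells to derive thresholds from.")
  tibble(analyte = analytes,
         threshold = unname(vapply(analytes, function(a) {
           unname(quantile(chip[[a]][zero], probs, type = 7))
         }, numeric(1))))
}

#' Arcsinh transform with threshold-linked cofactor
#'
#' `t(x) = asinh(x / (0.8 * threshold))`: approximately linear below the
#' cofactor, logarithmic above, defined for negative values, strictly
#' monotone.
#'
#' @param x Numeric values (a.f.u., normalized scale).
#' @param threshold Positive secretion threshold; the cofactor is
#'   `0.8 * threshold`.
#' @return Transformed values.
#' @export
transform_secretion <- function(x, threshold) {
  if (any(threshold <= 0)) abort("`threshold` must be positive.")
  asinh(x / (0.8 * threshold))
}

#' Secretion calls: normalized, transformed and thresholded intensities
#'
#' Applies the per-analyte thresholds to a normalized chip. A well is
#' positive for an analyte when its normalized intensity is strictly
#' above the threshold (the 99th percentile itself is background). The
#' arcsinh transform uses a cofactor of 0.8x threshold.
#'
#' @param chip A normalized [secretion_chip()].
#' @param thresholds A [compute_thresholds()] tibble (or named vector).
#' @return A `secretion_calls` object: `wells` tibble (well_id, row, col,
#'   cell_count), matrices `normalized`, `transformed`, logical
#'   `positive`, and `thresholds`.
#' @export
secretion_calls <- function(chip, thresholds = compute_thresholds(chip)) {
  stopifnot(inherits(chip, "secretion_chip"))
  analytes <- attr(chip, "analytes")
  thr <- if (is.data.frame(thresholds)) {
    setNames(thresholds$threshold, thresholds$analyte)[analytes]
  } else {
    thresholds[analytes]
  }
  if (anyNA(thr)) abort("Thresholds missing for some analytes.")
  if (any(thr <= 0)) abort("All thresholds must be positive for the transform.")
  normalized <- as.matrix(chip[, analytes, drop = FALSE])
  rownames(normalized) <- chip$well_id
  transformed <- sweep(normalized, 2L, 0.8 * thr, function(x, cf) asinh(x / cf))
  positive <- sweep(normalized, 2L, thr, `>`)
  structure(list(wells = chip[, c("well_id", "row", "col", "cell_count")],
                 normalized = normalized, transformed = transformed,
                 positive = positive, thresholds = thr),
            class = "secretion_calls")
}

#' @export
print.secretion_calls <- function(x, ...) {
  single <- x$wells$cell_count == 1
  cat(sprintf("<secretion_calls> %d wells (%d single-cell), %d analytes\n",
              nrow(x$wells), sum(single), ncol(x$normalized)))
  cat("  positive rate (single-cell wells):",
      paste(sprintf("%s %.1f%%", colnames(x$positive),
                    100 * colMeans(x$positive[single, , drop = FALSE])),
            collapse = ", "), "\n")
  invisible(x)
}

#' Single/double-positive fractions for analyte pairs
#'
#' Restricted to single-cell wells (`cell_count == 1`), reports for each
#' requested analyte pair the fractions of wells positive for only the
#' first, only the second, both, or neither analyte. Fractions sum to 1.
#'
#' @param calls A [secretion_calls()] result.
#' @param pairs List of length-2 character vectors, or a two-column data
#'   frame; `NULL` means all pairs.
#' @return Tibble (analyte_a, analyte_b, a_only, b_only, double_positive,
#'   double_negative, n_wells).
#' @export
call_and_quantify <- function(calls, pairs = NULL) {
  stopifnot(inherits(calls, "secretion_calls"))
  pos <- calls$positive[calls$wells$cell_count == 1, , drop = FALSE]
  analytes <- colnames(pos)
  if (is.null(pairs)) {
    pairs <- utils::combn(analytes, 2L, simplify = FALSE)
  } else if (is.data.frame(pairs)) {
    pairs <- purrr::pmap(pairs[, 1:2], ~ c(..1, ..2))
  }
  purrr::map_dfr(pairs, function(pr) {
    if (!all(pr %in% analytes)) {
      abort(sprintf("Unknown analyte in pair (%s, %s).", pr[1], pr[2]))
    }
    a <- pos[, pr[1]]; b <- pos[, pr[2]]
    tibble(analyte_a = pr[1], analyte_b = pr[2],
           a_only = mean(a & !b), b_only = mean(!a & b),
           double_positive = mean(a & b), double_negative = mean(!a & !b),
           n_wells = length(a))
  })
}

#' Pairwise odds ratios between secreted analytes
#'
#' Builds the boolean call matrix over single-cell wells and delegates to
#' [pairwise_odds_ratios()]. A significant negative log2 odds ratio means
#' the two analytes are secreted mutually exclusively.
#'
#' @param calls A [secretion_calls()] result.
#' @param features Optional analyte subset.
#' @param p_mask Masking level (default 0.05).
#' @return An `odds_ratio_result` with provenance `"secretion"`.
#' @export
secretion_odds_ratios <- function(calls, features = NULL, p_mask = 0.05) {
  stopifnot(inherits(calls, "secretion_calls"))
  single <- calls$wells$cell_count == 1
  bin <- structure(list(positive = calls$positive[single, , drop = FALSE],
                        thresholds = calls$thresholds,
                        provenance = "secretion"),
                   class = "binary_matrix")
  pairwise_odds_ratios(bin, features = features, p_mask = p_mask)
}

#' Run the full secretion processing chain
#'
#' normalize -> threshold -> transform -> call; returns the calls object
#' with the thresholds and window recorded.
#'
#' @param chip A raw [secretion_chip()].
#' @param window Background window (see [background_normalize()]).
#' @return A [secretion_calls()] object.
#' @export
process_chip <- function(chip, window = 50L) {
  normalized <- background_normalize(chip, window = window)
  secretion_calls(normalized, compute_thresholds(normalized))
}
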