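#' Consensus ensemble clustering of secretion profiles
#'
#' Runs a sweep of base clusterings (k-means, plus agglomerative
#' clustering with average, complete and Ward linkage on euclidean and
#' cosine distances, each across a range of k), builds the co-occurrence
#' matrix
#' (fraction of base partitions placing two wells in the same cluster),
#' and extracts the consensus by average-linkage agglomerative clustering
#' of `1 - co_occurrence`, cut at `cut_height`. Consensus clusters with
#' fewer than `min_size` members are discarded and their wells marked
#' unassigned (`NA`).
#'
#' @param x A numeric matrix (wells x analytes, typically arcsinh
#'   transformed) or a [secretion_calls()] object (its `transformed`
#'   matrix restricted to single-cell wells is used).
#' @param k_range Cluster counts swept by each base algorithm. The sweep
#'   should extend well past the expected number of groups: low-k
#'   partitions merge nearby profiles, and only the higher-k members let
#'   the co-occurrence matrix resolve them.
#' @param linkages,distances Agglomerative sweep members (`"ward"` uses
#'   Ward's criterion, euclidean distance only).
#' @param use_kmeans Include k-means in the sweep.
#' @param cut_height Cut on the `1 - co_occurrence` dendrogram. The
#'   default 0.4 is stricter than a bare majority because sweep families
#'   built on scale-invariant distances can be structurally blind to a
#'   contrast and vote "together" regardless of the data (see the methods
#'   vignette).
#' @param min_size Minimum consensus cluster size (default 3).
#' @param seed Seed for k-means initializations.
#' @return A `consensus_clustering`: `labels` tibble (well_id, cluster;
#'   `NA` cluster = unassigned), `co_occurrence` matrix, `partitions`
#'   tibble describing the sweep, `discarded` tibble of undersized
#'   clusters. `tidy()` returns labels; `glance()` a one-row summary.
#' @export
consensus_cluster <- function(x, k_range = 2:16,
                              linkages = c("average", "complete", "ward"),
                              distances = c("euclidean", "cosine"),
                              use_kmeans = TRUE,
                              cut_height = 0.4, min_size = 3L, seed = 1L) {
  if (inherits(x, "secretion_calls")) {
    single <- x$wells$cell_count == 1
    x <- x$transformed[single, , drop = FALSE]
  }
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("unit", seq_len(nrow(x)))
  if (ncol(x) < 2L) abort("Need at least 2 features to cluster.")
  if (nrow(x) < 10L) abort("Need at least 10 wells to cluster.")
  k_range <- k_range[k_range >= 1L & k_range < nrow(x)]
  if (!length(k_range)) abort("`k_range` leaves no usable k.")
  n <- nrow(x)

  # degenerate input: indistinguishable profiles form a single cluster by
  # definition (any k-partition of exact ties is arbitrary)
  if (all(x == rep(x[1, ], each = n))) {
    return(structure(
      list(labels = tibble(well_id = rownames(x), cluster = 1L),
           co_occurrence = matrix(1, n, n,
                                  dimnames = list(rownames(x), rownames(x))),
           partitions = tibble(algorithm = character(),
                               linkage = character(),
                               distance = character(), k = integer()),
           discarded = tibble(cluster_original = integer(), size = integer()),
           cut_height = cut_height, min_size = as.integer(min_size),
           data = x),
      class = "consensus_clustering"))
  }

  dist_mats <- lapply(setNames(distances, distances), function(d) {
    if (d == "euclidean") {
      dist(x)
    } else if (d == "cosine") {
      norms <- sqrt(rowSums(x^2))
      norms[norms == 0] <- 1
      sim <- tcrossprod(x / norms)
      as.dist(pmin(pmax(1 - sim, 0), 2))
    } else {
      abort(sprintf("Unsupported distance '%s'.", d))
    }
  })
  trees <- list()
  for (d in distances) {
    for (l in linkages) {
      if (l == "ward" && d != "euclidean") next   # ward assumes euclidean
      method <- if (l == "ward") "ward.D2" else l
      trees[[paste(l, d, sep = "/")]] <- hclust(dist_mats[[d]], method = method)
    }
  }

  partitions <- list()
  meta <- list()
  if (use_kmeans) {
    km_labels <- withr::with_seed(seed, {
      lapply(k_range, function(k) {
        if (k == 1L) rep(1L, n) else
          kmeans(x, centers = k, nstart = 5L, iter.max = 50L)$cluster
      })
    })
    for (i in seq_along(k_range)) {
      partitions[[length(partitions) + 1L]] <- km_labels[[i]]
      meta[[length(meta) + 1L]] <- tibble(algorithm = "kmeans",
                                          linkage = NA_character_,
                                          distance = "euclidean",
                                          k = k_range[i])
    }
  }
  for (nm in names(trees)) {
    parts <- strsplit(nm, "/")[[1]]
    for (k in k_range) {
      partitions[[length(partitions) + 1L]] <- cutree(trees[[nm]], k = k)
      meta[[length(meta) + 1L]] <- tibble(algorithm = "agglomerative",
                                          linkage = parts[1],
                                          distance = parts[2], k = k)
    }
  }
  if (!length(partitions)) abort("The clustering sweep is empty.")

  co <- matrix(0, n, n)
  for (lab in partitions) {
    ind <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(lab), x = 1)
    co <- co + as.matrix(Matrix::tcrossprod(ind))
  }
  co <- co / length(partitions)
  dimnames(co) <- list(rownames(x), rownames(x))

  cons_tree <- hclust(as.dist(1 - co), method = "average")
  if (is.unsorted(cons_tree$height)) {
    # guard against ~1e-16 non-monotonicity from tied averages
    cons_tree$height <- cummax(cons_tree$height)
  }
  cons <- cutree(cons_tree, h = cut_height)
  sizes <- table(cons)
  small <- as.integer(names(sizes)[sizes < min_size])
  labels <- tibble(well_id = rownames(x),
                   cluster = ifelse(cons %in% small, NA_integer_,
                                    as.integer(cons)))
  # renumber retained clusters by decreasing size
  keep <- sort(table(labels$cluster), decreasing = TRUE)
  remap <- setNames(seq_along(keep), names(keep))
  labels$cluster <- as.integer(remap[as.character(labels$cluster)])
  discarded <- tibble(cluster_original = small,
                      size = as.integer(sizes[as.character(small)]))
  structure(list(labels = labels, co_occurrence = co,
                 partitions = bind_rows(meta), discarded = discarded,
                 cut_height = cut_height, min_size = as.integer(min_size),
                 data = x),
            class = "consensus_clustering")
}

#' @export
print.consensus_clustering <- function(x, ...) {
  k <- length(unique(stats::na.omit(x$labels$cluster)))
  cat(sprintf("<consensus_clustering> %d wells, %d base partitions -> %d consensus clusters (%d wells unassigned)\n",
              nrow(x$labels), nrow(x$partitions), k,
              sum(is.na(x$labels$cluster))))
  invisible(x)
}

#' @method tidy consensus_clustering
#' @export
tidy.consensus_clustering <- function(x, ...) x$labels

#' @method glance consensus_clustering
#' @export
glance.consensus_clustering <- function(x, ...) {
  tibble(n_wells = nrow(x$labels),
         n_clusters = length(unique(stats::na.omit(x$labels$cluster))),
         n_unassigned = sum(is.na(x$labels$cluster)),
         n_partitions = nrow(x$partitions),
         cut_height = x$cut_height,
         min_size = x$min_size)
}

#' Cluster-level secretion summary
#'
#' Mean transformed intensity per analyte within each consensus cluster,
#' with cluster sizes and fractions (the cluster-fraction bar-chart /
#' profile-heatmap companion).
#'
#' @param clustering A [consensus_cluster()] result.
#' @return Tibble (cluster, n_wells, fraction, then one column per
#'   analyte).
#' @export
cluster_profiles <- function(clustering) {
  stopifnot(inherits(clustering, "consensus_clustering"))
  lab <- clustering$labels
  x <- clustering$data
  assigned <- !is.na(lab$cluster)
  purrr::map_dfr(sort(unique(lab$cluster[assigned])), function(k) {
    rows <- which(assigned & lab$cluster == k)
    out <- tibble(cluster = k, n_wells = length(rows),
                  fraction = length(rows) / sum(assigned))
    for (a in colnames(x)) out[[a]] <- mean(x[rows, a])
    out
  })
}
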