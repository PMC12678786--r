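#' Ward hierarchical clustering of a state or LSS matrix
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances — each merge is the pair whose fusion least increases
#' the within-cluster sum of squares. Binary 0/1 state rows are valid input
#' (Euclidean distance on them is the square root of the Hamming distance);
#' continuous LSS values are equally supported.
#'
#' @param x Numeric matrix, genes in rows and samples in columns; no missing
#'   values.
#' @param axis `"samples"` (cluster columns; default) or `"genes"` (rows).
#' @return Object of class `ward_clust` wrapping the `hclust` tree plus
#'   `axis`, `labels`, `method = "ward"`, `metric = "euclidean"`.
#' @export
ward_cluster <- function(x, axis = c("samples", "genes")) {
  axis <- match.arg(axis)
  x <- unclass(as.matrix(x))
  if (anyNA(x)) stop("matrix contains missing values")
  pts <- if (axis == "samples") t(x) else x
  if (nrow(pts) < 2L) stop("need at least 2 ", axis, " to cluster")
  hc <- stats::hclust(stats::dist(pts, method = "euclidean"),
                      method = "ward.D2")
  structure(list(hclust = hc, axis = axis, labels = hc$labels,
                 leaf_order = hc$order, method = "ward",
                 metric = "euclidean"),
            class = "ward_clust")
}

#' @export
print.ward_clust <- function(x, ...) {
  cat(sprintf("ward_clust over %s: %d leaves, %d merges (Ward / Euclidean)\n",
              x$axis, length(x$leaf_order), nrow(x$hclust$merge)))
  invisible(x)
}

#' Cut a Ward tree into k clusters
#'
#' Removes the `k - 1` highest merges and labels the resulting groups 1..k
#' in dendrogram leaf order (the leftmost leaf's cluster is 1), so ids are
#' stable and contiguous.
#'
#' @param result A [ward_cluster()] tree.
#' @param k Number of clusters, `1 <= k <=` number of leaves.
#' @return Named integer vector of cluster ids.
#' @export
cut_clusters <- function(result, k) {
  stopifnot(inherits(result, "ward_clust"))
  n <- length(result$leaf_order)
  if (k < 1L || k > n) stop("k must lie in [1, ", n, "]")
  raw <- stats::cutree(result$hclust, k = k)
  first_seen <- raw[result$leaf_order]
  relabel <- stats::setNames(seq_along(unique(first_seen)),
                             unique(first_seen))
  out <- as.integer(relabel[as.character(raw)])
  names(out) <- names(raw)
  out
}

#' Majority-label classification rate of unsupervised clusters
#'
#' Each cluster is assigned its majority true label; the rate is the share
#' of samples whose label matches their cluster's majority, as a percentage.
#' It is invariant to cluster relabeling and to sample order. A within-
#' cluster majority tie resolves toward the alphabetically first label and
#' is flagged.
#'
#' @param cluster Integer/character cluster id per sample.
#' @param truth True label per sample (same length/order).
#' @return Object of class `classification_rate`: `rate` (raw percentage),
#'   `rate_rounded` (nearest integer), `majority` (label per cluster),
#'   `ties` (cluster ids with tied majorities), `n`.
#' @export
classification_rate <- function(cluster, truth) {
  if (length(cluster) != length(truth))
    stop("cluster and truth lengths differ")
  if (length(cluster) == 0L) stop("need at least one sample")
  truth <- as.character(truth)
  correct <- 0L
  majority <- list(); ties <- character()
  for (cl in unique(cluster)) {
    tab <- table(truth[cluster == cl])
    top <- max(tab)
    winners <- sort(names(tab)[tab == top])
    if (length(winners) > 1L) ties <- c(ties, as.character(cl))
    majority[[as.character(cl)]] <- winners[1L]
    correct <- correct + top
  }
  rate <- 100 * correct / length(cluster)
  structure(list(rate = rate, rate_rounded = round(rate),
                 majority = unlist(majority), ties = ties,
                 n = length(cluster)),
            class = "classification_rate")
}

#' @export
print.classification_rate <- function(x, ...) {
  cat(sprintf("classification rate: %.2f%% (%d%%) over %d samples\n",
              x$rate, x$rate_rounded, x$n))
  if (length(x$ties))
    cat("  tied majorities in cluster(s): ", paste(x$ties, collapse = ", "),
        " (alphabetic resolution)\n", sep = "")
  invisible(x)
}
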