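## Unsupervised discovery of harmonization labels: agglomerative
## clustering under Euclidean distance with silhouette-scored selection of
## the number of clusters. Used when acquisition settings are too
## heterogeneous to assign center labels by hand.

linkage_method <- function(linkage = c("ward", "average", "complete")) {
  switch(match.arg(linkage), ward = "ward.D2", average = "average",
         complete = "complete")
}

## z-score features before computing distances: radiomic features span
## wildly different units and unscaled Euclidean distance is dominated by
## the large-scale ones. Constant features carry no distance information
## and are dropped.
scaled_dist <- function(values, scale. = TRUE) {
  if (scale.) {
    sds <- apply(values, 2L, stats::sd)
    keep <- sds > 0
    if (!any(keep)) stop("all features are constant", call. = FALSE)
    values <- scale(values[, keep, drop = FALSE])
  }
  stats::dist(values)
}

#' Agglomerative clustering of samples
#'
#' Deterministic hierarchical clustering of samples under Euclidean
#' distance on per-feature z-scored data, cut at `k` clusters.
#'
#' @param values numeric samples-by-features matrix.
#' @param k number of clusters, `2 <= k <= n_samples - 1`.
#' @param linkage `"ward"` (minimum variance, default), `"average"`, or
#'   `"complete"`.
#' @param scale. z-score features before computing distances.
#' @return Factor of cluster labels (`"1" ... "k"`), with the `"hclust"`
#'   tree as attribute `"tree"`.
#' @export
hierarchical_cluster <- function(values, k, linkage = "ward", scale. = TRUE) {
  values <- check_values(values)
  if (k < 2L || k > nrow(values) - 1L)
    stop("'k' must be in [2, n_samples - 1]", call. = FALSE)
  tree <- stats::hclust(scaled_dist(values, scale.), method =
                          linkage_method(linkage))
  labels <- factor(stats::cutree(tree, k = k))
  attr(labels, "tree") <- tree
  labels
}

#' Select the number of harmonization labels by mean silhouette width
#'
#' Cuts one agglomerative tree at every `k` in `k_range`, scores each
#' partition by the mean silhouette width `s(x) = (b - a) / max(a, b)`
#' under Euclidean distance, and picks the `k` with the largest mean
#' silhouette (ties broken toward smaller `k`: fewer labels leave more
#' samples per batch for the harmonization fit).
#'
#' @param values numeric samples-by-features matrix.
#' @param k_range integer candidate numbers of clusters (default
#'   `2:min(10, n - 1)`).
#' @param linkage,scale. see [hierarchical_cluster()].
#' @param outcome optional binary outcome; when given, the per-cluster
#'   event rates are checked with [outcome_balance_check()].
#' @return An object of class `"cluster_selection"`: `tree`,
#'   `silhouette_by_k` (named vector), `chosen_k`, `labels` (factor), and
#'   `outcome_balance` (or `NULL`).
#' @export
silhouette_select_k <- function(values, k_range = NULL, linkage = "ward",
                                scale. = TRUE, outcome = NULL) {
  values <- check_values(values)
  n <- nrow(values)
  if (n < 4L)
    stop("silhouette selection needs at least 4 samples", call. = FALSE)
  if (is.null(k_range)) k_range <- 2:min(10L, n - 1L)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L || max(k_range) > n - 1L)
    stop("'k_range' must lie within [2, n_samples - 1]", call. = FALSE)

  d <- scaled_dist(values, scale.)
  tree <- stats::hclust(d, method = linkage_method(linkage))
  sil <- vapply(k_range, function(k) {
    cl <- stats::cutree(tree, k = k)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  names(sil) <- k_range

  chosen_k <- k_range[which.max(sil)]  # which.max: first max -> smallest k
  labels <- factor(stats::cutree(tree, k = chosen_k))
  balance <- if (!is.null(outcome)) outcome_balance_check(labels, outcome)

  structure(list(tree = tree, silhouette_by_k = sil, chosen_k = chosen_k,
                 labels = labels, outcome_balance = balance),
            class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat("Silhouette-selected clustering\n")
  cat("  mean silhouette by k:",
      paste(sprintf("%s: %.3f", names(x$silhouette_by_k), x$silhouette_by_k),
            collapse = ", "), "\n")
  tab <- table(x$labels)
  cat(sprintf("  chosen k = %d (cluster sizes: %s)\n", x$chosen_k,
              paste(tab, collapse = ", ")))
  if (!is.null(x$outcome_balance)) print(x$outcome_balance)
  invisible(x)
}

#' Check discovered clusters for outcome confounding
#'
#' Discovered harmonization labels should reflect acquisition differences,
#' not the clinical endpoint. This reports the event rate per cluster and
#' flags the partition when rates differ more than expected by chance
#' (two-proportion / k-proportion test), warning that the clusters may
#' encode outcome rather than a center effect.
#'
#' @param labels per-sample cluster labels.
#' @param outcome binary (0/1) outcome vector aligned with `labels`.
#' @param alpha flagging threshold on the proportion-test p-value.
#' @return A list with `rates` (per-cluster event rates), `events`,
#'   `sizes`, `p_value`, and `flagged`.
#' @export
outcome_balance_check <- function(labels, outcome, alpha = 0.05) {
  labels <- factor(labels)
  if (length(outcome) != length(labels))
    stop("'outcome' not aligned with 'labels'", call. = FALSE)
  if (!all(outcome %in% c(0, 1)))
    stop("'outcome' must be binary 0/1", call. = FALSE)
  events <- tapply(outcome, labels, sum)
  sizes <- as.vector(table(labels))
  rates <- as.vector(events) / sizes
  p <- if (all(as.vector(events) %in% c(0, sizes))) {
    ## degenerate all-or-none clusters: prop.test is undefined, but equal
    ## all-zero (or all-one) rates are perfectly balanced
    if (length(unique(rates)) == 1L) 1 else 0
  } else
    suppressWarnings(stats::prop.test(as.vector(events), sizes)$p.value)
  structure(list(rates = stats::setNames(rates, levels(labels)),
                 events = as.vector(events), sizes = sizes,
                 p_value = p, flagged = p < alpha, alpha = alpha),
            class = "outcome_balance")
}

#' @export
print.outcome_balance <- function(x, ...) {
  cat("  event rate per cluster:",
      paste(sprintf("%s: %d/%d (%.1f%%)", names(x$rates), x$events, x$sizes,
                    100 * x$rates), collapse = ", "), "\n")
  cat(sprintf("  proportion test p = %.3g%s\n", x$p_value,
              if (x$flagged)
                " -- FLAG: clusters may encode outcome, not center effect"
              else ""))
  invisible(x)
}
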