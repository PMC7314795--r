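## Harmonization-quality battery: per-feature ANOVA across labels,
## aggregate coefficient of variation, top-2 PCA summary, and the
## confusion-matrix metrics used to score the downstream classifiers.

#' Per-feature one-way ANOVA across labels
#'
#' Classic equal-variance fixed-effects F-test of each feature's
#' distribution across batch labels, plus the fraction of features
#' significant at `alpha` (raw p-values, no multiplicity correction).
#'
#' @param values numeric samples-by-features matrix.
#' @param labels per-sample group labels (>= 2 groups, each >= 2 samples).
#' @param alpha significance threshold (default 0.01).
#' @return A list with `p` (named per-feature p-values),
#'   `frac_significant`, and `alpha`.
#' @export
per_feature_anova <- function(values, labels, alpha = 0.01) {
  values <- check_values(values)
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2L) stop("need >= 2 labels", call. = FALSE)
  if (any(table(labels) < 2L))
    stop("every label needs >= 2 samples", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)

  p <- apply(values, 2L, function(x) {
    if (stats::var(x) == 0) return(1)  # no variance at all: no group effect
    stats::oneway.test(x ~ labels, var.equal = TRUE)$p.value
  })
  p[is.na(p)] <- 1  # zero within-group variance with zero between: F = 0/0
  list(p = p, frac_significant = mean(p < alpha), alpha = alpha)
}

#' Aggregate coefficient of variation of a feature table
#'
#' Sums the per-feature absolute percent coefficients of variation,
#' `sum_g |sd_g / mean_g| * 100`, yielding one dispersion scalar per
#' table. Features with zero mean have an undefined COV and are excluded
#' with a warning; constant features contribute zero.
#'
#' @param values numeric samples-by-features matrix.
#' @return A single non-negative scalar.
#' @export
aggregate_cov <- function(values) {
  values <- check_values(values)
  m <- colMeans(values)
  s <- apply(values, 2L, stats::sd)
  zero_mean <- m == 0
  if (all(zero_mean)) stop("all features have zero mean; COV undefined",
                           call. = FALSE)
  if (any(zero_mean))
    warning(sum(zero_mean), " zero-mean feature(s) excluded from COV",
            call. = FALSE)
  sum(abs(s[!zero_mean] / m[!zero_mean]) * 100)
}

#' Top-2 principal component summary
#'
#' PCA on centered, z-scored features (correlation PCA: unscaled axes
#' would be dominated by the large-unit features). Constant features are
#' dropped. The sign of each component is fixed so the largest-magnitude
#' loading is positive, making the scores deterministic.
#'
#' @param values numeric samples-by-features matrix, `n >= 3`.
#' @param scale. z-score features (default `TRUE`).
#' @return A list with `scores` (n x 2), `explained` (two variance
#'   fractions, non-increasing), and `loadings` (features x 2).
#' @export
pca_top2 <- function(values, scale. = TRUE) {
  values <- check_values(values, min_samples = 3L)
  sds <- apply(values, 2L, stats::sd)
  values <- values[, sds > 0, drop = FALSE]
  if (ncol(values) < 1L) stop("no non-constant features", call. = FALSE)
  pc <- stats::prcomp(values, center = TRUE, scale. = scale.)
  if (ncol(pc$x) < 2L)
    stop("fewer than 2 non-degenerate dimensions", call. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, 1:2, drop = FALSE]
  loadings <- pc$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    flip <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (flip < 0) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  list(scores = scores, explained = explained[1:2], loadings = loadings)
}

#' Confusion-matrix counts
#'
#' @param truth true binary labels (0/1 or two-level factor).
#' @param pred predicted binary labels on the same coding.
#' @param positive value of the positive class (default `1` or the second
#'   factor level).
#' @return A list of class `"confusion_counts"` with `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion_counts <- function(truth, pred, positive = NULL) {
  if (length(truth) != length(pred))
    stop("'truth' and 'pred' lengths differ", call. = FALSE)
  if (is.null(positive))
    positive <- if (is.factor(truth)) levels(truth)[nlevels(truth)] else 1
  t_pos <- truth == positive
  p_pos <- pred == positive
  structure(list(tp = sum(t_pos & p_pos), fp = sum(!t_pos & p_pos),
                 tn = sum(!t_pos & !p_pos), fn = sum(t_pos & !p_pos)),
            class = "confusion_counts")
}

check_counts <- function(c) {
  stopifnot(is.list(c), all(c(c$tp, c$fp, c$tn, c$fn) >= 0))
  if (c$tp + c$fn < 1L) stop("empty positive class", call. = FALSE)
  if (c$tn + c$fp < 1L) stop("empty negative class", call. = FALSE)
  c
}

#' Balanced accuracy
#'
#' The mean of sensitivity and specificity,
#' `(tp/(tp+fn) + tn/(tn+fp)) / 2`; robust to class imbalance, unlike raw
#' accuracy.
#'
#' @param counts a `"confusion_counts"` object (see [confusion_counts()]).
#' @return A value in `[0, 1]`.
#' @export
balanced_accuracy <- function(counts) {
  c <- check_counts(counts)
  (c$tp / (c$tp + c$fn) + c$tn / (c$tn + c$fp)) / 2
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, in `[-1, 1]`
#' (worst -1, chance 0, best +1); defined as 0 when any marginal is zero.
#'
#' @param counts a `"confusion_counts"` object.
#' @return A value in `[-1, 1]`.
#' @export
matthews_cc <- function(counts) {
  c <- check_counts(counts)
  marg <- c(c$tp + c$fp, c$tp + c$fn, c$tn + c$fp, c$tn + c$fn)
  if (any(marg == 0)) return(0)
  (c$tp * c$tn - c$fp * c$fn) / sqrt(prod(marg))
}

#' Full harmonization-quality report
#'
#' Bundles the battery: per-feature ANOVA across labels, aggregate COV,
#' top-2 PCA, and per-label per-feature means and SDs.
#'
#' @param values numeric samples-by-features matrix.
#' @param labels per-sample batch/cluster labels.
#' @param alpha ANOVA significance threshold.
#' @return An object of class `"evaluation_report"`.
#' @export
evaluate_harmonization <- function(values, labels, alpha = 0.01) {
  values <- check_values(values, min_samples = 3L)
  labels <- factor(as.character(labels))
  anova <- per_feature_anova(values, labels, alpha)
  pca <- pca_top2(values)
  per_label <- lapply(levels(labels), function(l) {
    vi <- values[labels == l, , drop = FALSE]
    list(mean = colMeans(vi), sd = apply(vi, 2L, stats::sd))
  })
  names(per_label) <- levels(labels)
  structure(list(anova_p = anova$p, frac_significant = anova$frac_significant,
                 alpha = alpha, cov_aggregate = aggregate_cov(values),
                 pca_scores = pca$scores, pca_explained = pca$explained,
                 per_label_summaries = per_label),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Harmonization evaluation report\n")
  cat(sprintf("  ANOVA: %.1f%% of features significant at p < %g\n",
              100 * x$frac_significant, x$alpha))
  cat(sprintf("  aggregate COV: %.1f\n", x$cov_aggregate))
  cat(sprintf("  top-2 PCA explained variance: %.1f%% + %.1f%%\n",
              100 * x$pca_explained[1], 100 * x$pca_explained[2]))
  invisible(x)
}
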