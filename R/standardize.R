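## Location-scale standardization and raw batch-effect estimation.
##
## Conventions (pinned; the cross-check tests assert them):
##  - grand mode: alpha_g is the batch-size-weighted mean of per-batch OLS
##    intercepts, sigma2_g the mean squared residual over ALL samples
##    (population 1/n divisor) from the joint batch+covariate fit;
##  - reference mode: alpha_g and sigma2_g come from the reference batch
##    only, with the sample (n_r - 1) divisor so the reference batch
##    standardizes to exactly unit spread;
##  - delta2_hat uses the within-batch sample variance (n_i - 1 divisor).

batch_design_matrix <- function(batch, covariates = NULL) {
  bm <- if (nlevels(batch) == 1L)
    matrix(1, length(batch), 1L)
  else stats::model.matrix(~ 0 + batch)
  colnames(bm) <- levels(batch)
  if (!is.null(covariates)) {
    d <- cbind(bm, covariates)
    if (qr(d)$rank < ncol(d))
      stop("covariates are confounded with batch; remove the offending covariate",
           call. = FALSE)
    d
  } else bm
}

#' Standardize a feature table for batch-effect estimation
#'
#' Centers and scales each feature with ordinary least squares so that the
#' batch effects become a location-scale perturbation of a standard-normal
#' variable. In `"grand"` mode (classic ComBat) the center is the
#' batch-size-weighted grand mean and the scale the pooled residual
#' standard deviation, shared by all samples. In `"batchwise"` mode
#' (M-ComBat) every batch is standardized by its own per-batch mean and
#' spread, so each batch maps to mean zero and unit scale; the reference
#' batch's moments are restored at adjustment time.
#'
#' @param values numeric samples-by-features matrix.
#' @param batch per-sample batch labels (coerced to factor).
#' @param covariates optional numeric covariate matrix `X`; its effect
#'   `X beta_g` is estimated jointly with the batch means and removed
#'   before scaling.
#' @param mode `"grand"` or `"batchwise"`.
#' @return A list with `z` (standardized matrix), `alpha` (per-feature
#'   location: a vector in grand mode, a batches-by-features matrix in
#'   batchwise mode), `sigma2` (squared scale, same shape as `alpha`),
#'   `beta` (covariate coefficients or `NULL`), `mode`, `batch_levels`,
#'   and `stand_mean` (the per-sample location removed before scaling).
#' @export
fit_standardization <- function(values, batch, covariates = NULL,
                                mode = c("grand", "batchwise")) {
  mode <- match.arg(mode)
  values <- check_values(values)
  batch <- check_batch(batch, nrow(values), warn_small = FALSE)
  covariates <- check_covariates(covariates, nrow(values))
  lv <- levels(batch)

  design <- batch_design_matrix(batch, covariates)
  b_hat <- solve(crossprod(design), crossprod(design, values))
  resid <- values - design %*% b_hat
  n_i <- as.vector(table(batch))
  n <- nrow(values)
  ib <- as.integer(batch)

  beta <- if (!is.null(covariates)) {
    b <- b_hat[-seq_along(lv), , drop = FALSE]
    rownames(b) <- colnames(covariates)
    b
  }

  if (mode == "grand") {
    alpha <- as.vector((n_i / n) %*% b_hat[seq_along(lv), , drop = FALSE])
    sigma2 <- colSums(resid^2) / n  # population divisor over all samples
    names(alpha) <- names(sigma2) <- colnames(values)
    if (any(sigma2 <= 0 | !is.finite(sigma2)))
      stop("zero residual variance for feature(s): ",
           paste(colnames(values)[sigma2 <= 0], collapse = ", "),
           call. = FALSE)
    stand_mean <- matrix(alpha, n, ncol(values), byrow = TRUE)
    if (!is.null(covariates)) stand_mean <- stand_mean + covariates %*% beta
    scale_mat <- matrix(sqrt(sigma2), n, ncol(values), byrow = TRUE)
  } else {
    alpha <- b_hat[seq_along(lv), , drop = FALSE]  # per-batch intercepts
    rownames(alpha) <- lv
    sigma2 <- do.call(rbind, lapply(seq_along(lv), function(i)
      colSums(resid[ib == i, , drop = FALSE]^2) / (n_i[i] - 1L)))
    dimnames(sigma2) <- list(lv, colnames(values))
    if (any(sigma2 <= 0 | !is.finite(sigma2))) {
      bad <- unique(colnames(values)[which(sigma2 <= 0, arr.ind = TRUE)[, 2]])
      stop("zero within-batch variance for feature(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    stand_mean <- alpha[ib, , drop = FALSE]
    if (!is.null(covariates)) stand_mean <- stand_mean + covariates %*% beta
    scale_mat <- sqrt(sigma2)[ib, , drop = FALSE]
  }
  z <- (values - stand_mean) / scale_mat
  dimnames(z) <- dimnames(values)

  list(z = z, alpha = alpha, beta = beta, sigma2 = sigma2, mode = mode,
       batch_levels = lv, stand_mean = stand_mean)
}

#' Estimate raw per-batch location-scale effects
#'
#' On standardized data, the raw batch effect of batch `i` on feature `g`
#' is the within-batch mean (`gamma_hat`) and the within-batch sample
#' variance (`delta2_hat`) of the standardized values.
#'
#' @param z standardized matrix from [fit_standardization()].
#' @param batch per-sample batch labels.
#' @return A list with matrices `gamma_hat` and `delta2_hat` (batches in
#'   rows, features in columns) and the per-batch sample counts `n_i`.
#' @export
estimate_batch_effects <- function(z, batch) {
  if (!is.matrix(z) || !is.numeric(z)) stop("'z' must be a numeric matrix",
                                            call. = FALSE)
  batch <- check_batch(batch, nrow(z), warn_small = FALSE)
  lv <- levels(batch)
  tab <- table(batch)
  if (any(tab < 2L))
    stop("within-batch variance undefined: batch(es) with a single sample: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)

  gamma_hat <- do.call(rbind, lapply(lv, function(l)
    colMeans(z[batch == l, , drop = FALSE])))
  delta2_hat <- do.call(rbind, lapply(lv, function(l) {
    zi <- z[batch == l, , drop = FALSE]
    colSums(sweep(zi, 2L, colMeans(zi))^2) / (nrow(zi) - 1L)
  }))
  dimnames(gamma_hat) <- dimnames(delta2_hat) <- list(lv, colnames(z))

  if (any(delta2_hat <= 0)) {
    bad <- which(delta2_hat <= 0, arr.ind = TRUE)
    stop("zero within-batch variance (batch '", lv[bad[1, 1]], "', feature '",
         colnames(z)[bad[1, 2]], "'); drop degenerate features first",
         call. = FALSE)
  }
  list(gamma_hat = gamma_hat, delta2_hat = delta2_hat, n_i = as.vector(tab))
}

## feature indices with zero within-batch variance in any batch (degenerate
## for the location-scale model)
degenerate_features <- function(values, batch) {
  batch <- factor(as.character(batch))
  bad <- logical(ncol(values))
  for (l in levels(batch)) {
    vi <- values[batch == l, , drop = FALSE]
    if (nrow(vi) > 1L)
      bad <- bad | apply(vi, 2L, function(x) stats::var(x) == 0)
  }
  which(bad)
}
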