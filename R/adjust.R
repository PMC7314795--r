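## Batch-effect adjustment and bootstrap-stabilized estimation.

## location/scale used on the way back out: pooled (grand) or the
## reference batch's row (batchwise)
adjust_targets <- function(std, reference = NULL) {
  if (std$mode == "grand")
    return(list(alpha = std$alpha, sigma2 = std$sigma2))
  if (is.null(reference))
    stop("'reference' is required to adjust batchwise-standardized data",
         call. = FALSE)
  reference <- as.character(reference)
  if (!reference %in% rownames(std$alpha))
    stop("reference batch '", reference, "' not among batch labels",
         call. = FALSE)
  list(alpha = std$alpha[reference, ], sigma2 = std$sigma2[reference, ])
}

#' Remove estimated batch effects from standardized data
#'
#' Applies the location-scale correction: each standardized value has its
#' batch's (shrunken) location effect subtracted and its spread divided by
#' the batch's (shrunken) scale effect, then the feature is mapped back to
#' the pooled location/scale (grand mode) or the reference batch's
#' location/scale (batchwise mode, M-ComBat).
#'
#' @param z standardized matrix from [fit_standardization()].
#' @param std standardization fit (provides `alpha`, `sigma2`, `beta` and
#'   the per-sample location to add back).
#' @param effects shrunken effects from [fit_priors_and_shrink()] (or raw
#'   effects when diagnosing with `prior = "none"`).
#' @param batch per-sample batch labels; every label must have been seen at
#'   fit time (the model cannot extrapolate to unseen batches).
#' @param covariates covariate matrix for these samples, when the model was
#'   fit with covariates.
#' @param reference reference batch label (batchwise mode only).
#' @return Numeric matrix of harmonized values, same shape and dimnames as
#'   `z`.
#' @export
adjust_data <- function(z, std, effects, batch, covariates = NULL,
                        reference = NULL) {
  batch <- factor(as.character(batch))
  unseen <- setdiff(levels(batch), rownames(effects$gamma_star))
  if (length(unseen))
    stop("batch label(s) not seen at fit time: ",
         paste(unseen, collapse = ", "),
         "; ComBat cannot extrapolate to unseen batches", call. = FALSE)
  n <- nrow(z)
  G <- ncol(z)
  idx <- match(as.character(batch), rownames(effects$gamma_star))
  tgt <- adjust_targets(std, reference)

  stand_mean <- matrix(tgt$alpha, n, G, byrow = TRUE)
  if (!is.null(std$beta)) {
    if (is.null(covariates))
      stop("model was fit with covariates; supply 'covariates'", call. = FALSE)
    stand_mean <- stand_mean + as.matrix(covariates) %*% std$beta
  }
  scale_fac <- matrix(sqrt(tgt$sigma2), n, G, byrow = TRUE) /
    sqrt(effects$delta2_star[idx, , drop = FALSE])
  out <- scale_fac * (z - effects$gamma_star[idx, , drop = FALSE]) + stand_mean
  dimnames(out) <- dimnames(z)
  out
}

## Full single fit: standardize -> raw effects -> shrink. Shared by
## harmonize() and every bootstrap replicate.
combat_single_fit <- function(values, batch, covariates, mode,
                              prior, conv = 1e-4, max_iter = 100L) {
  std <- fit_standardization(values, batch, covariates, mode)
  eff <- estimate_batch_effects(std$z, batch)
  shr <- fit_priors_and_shrink(eff, prior, z = std$z, batch = batch,
                               conv = conv, max_iter = max_iter)
  list(std = std, effects = shr)
}

#' Bootstrap-stabilized ComBat estimation
#'
#' Resamples the cohort `B` times (stratified within batch, with
#' replacement), refits the full ComBat (or M-ComBat) estimation on each
#' resample, and returns the Monte-Carlo averages of all coefficients
#' (location `alpha`, covariate `beta`, scale `sigma`, shrunken batch
#' effects `gamma_star`, `delta_star`). Averaging is done on the
#' standard-deviation scale for the scale coefficients, the scale on which
#' they enter the adjustment. Resamples in which some batch loses all
#' spread on a feature are redrawn and counted.
#'
#' @param values,batch,covariates data as in [harmonize()].
#' @param mode `"grand"` or `"batchwise"` standardization.
#' @param B number of bootstrap resamples (the stabilized estimate is the
#'   mean over all `B`).
#' @param seed integer seed governing all resampling.
#' @param prior prior mode passed to each refit.
#' @param bootstrap_mode `"case"` (default): stratified case resampling;
#'   `"parametric"`: resamples are drawn from the fitted Normal
#'   location-scale model instead.
#' @param conv,max_iter parametric-iteration controls.
#' @return A list with the averaged coefficient set (`alpha`, `beta`,
#'   `sigma2`, `gamma_star`, `delta2_star`), the across-replicate spread
#'   of the location effects (`gamma_rep_var`), the point-estimate fit
#'   (`point_fit`), and diagnostics (`B`, `seed`, `n_redraws`).
#' @export
bootstrap_fit <- function(values, batch, covariates = NULL,
                          mode = c("grand", "batchwise"),
                          B = 1000L, seed, prior = "nonparametric",
                          bootstrap_mode = c("case", "parametric"),
                          conv = 1e-4, max_iter = 100L) {
  mode <- match.arg(mode)
  bootstrap_mode <- match.arg(bootstrap_mode)
  if (B < 1L) stop("'B' must be >= 1", call. = FALSE)
  if (missing(seed) || is.null(seed))
    stop("bootstrap estimation requires an integer 'seed'", call. = FALSE)
  values <- check_values(values)
  batch <- check_batch(batch, nrow(values), min_per_batch = 3L,
                       warn_small = FALSE)
  lv <- levels(batch)
  rows_by_batch <- lapply(lv, function(l) which(batch == l))

  point <- combat_single_fit(values, batch, covariates, mode, prior,
                             conv, max_iter)

  set.seed(as.integer(seed))
  n <- nrow(values)
  G <- ncol(values)
  p <- if (is.null(covariates)) 0L else ncol(covariates)

  ## alpha/sigma follow the standardization-mode shape (vector in grand
  ## mode, batches x features in batchwise mode)
  alpha_sum <- point$std$alpha * 0
  sigma_sum <- point$std$sigma2 * 0
  beta_sum <- if (p) matrix(0, p, G)
  gamma_sum <- matrix(0, length(lv), G)
  gamma_ss <- matrix(0, length(lv), G)  # replicate spread diagnostics
  delta_sum <- matrix(0, length(lv), G)
  n_redraws <- 0L
  max_redraws <- ceiling(0.5 * B)

  draw <- function() {
    if (bootstrap_mode == "case") {
      idx <- unlist(lapply(rows_by_batch, function(r)
        r[sample.int(length(r), length(r), replace = TRUE)]))
      list(values = values[idx, , drop = FALSE], batch = batch[idx],
           covariates = if (p) covariates[idx, , drop = FALSE])
    } else {
      eps <- matrix(stats::rnorm(n * G), n, G)
      ib <- match(as.character(batch), lv)
      scale_mat <- if (mode == "grand")
        matrix(sqrt(point$std$sigma2), n, G, byrow = TRUE)
      else sqrt(point$std$sigma2)[ib, , drop = FALSE]
      sim <- point$std$stand_mean + scale_mat *
        (point$effects$gamma_hat[ib, , drop = FALSE] +
           sqrt(point$effects$delta2_hat[ib, , drop = FALSE]) * eps)
      dimnames(sim) <- dimnames(values)
      list(values = sim, batch = batch, covariates = covariates)
    }
  }

  for (k in seq_len(B)) {
    repeat {
      d <- draw()
      rownames(d$values) <- rownames(values)  # resampled rows need unique IDs
      ok <- length(degenerate_features(d$values, d$batch)) == 0L
      if (ok) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > max_redraws)
        stop("more than 50% of bootstrap resamples were degenerate; ",
             "use larger batches or a smaller B", call. = FALSE)
    }
    fit_k <- combat_single_fit(d$values, d$batch, d$covariates, mode,
                               prior, conv, max_iter)
    alpha_sum <- alpha_sum + fit_k$std$alpha
    sigma_sum <- sigma_sum + sqrt(fit_k$std$sigma2)
    if (p) beta_sum <- beta_sum + fit_k$std$beta
    gamma_sum <- gamma_sum + fit_k$effects$gamma_star
    gamma_ss <- gamma_ss + fit_k$effects$gamma_star^2
    delta_sum <- delta_sum + sqrt(fit_k$effects$delta2_star)
  }

  gamma_star <- gamma_sum / B
  gamma_rep_var <- if (B > 1L)
    (gamma_ss - B * gamma_star^2) / (B - 1L)
  else matrix(NA_real_, length(lv), G)
  delta2_star <- (delta_sum / B)^2
  dimnames(gamma_star) <- dimnames(delta2_star) <-
    dimnames(point$effects$gamma_star)
  beta <- if (p) {
    b <- beta_sum / B
    dimnames(b) <- dimnames(point$std$beta)
    b
  }
  list(alpha = alpha_sum / B, beta = beta, sigma2 = (sigma_sum / B)^2,
       mode = mode, gamma_star = gamma_star, delta2_star = delta2_star,
       gamma_rep_var = gamma_rep_var,
       point_fit = point, B = B, seed = as.integer(seed),
       bootstrap_mode = bootstrap_mode, n_redraws = n_redraws)
}
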