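## The main fitting function and the "radharmony" model class.

## Apply a stored coefficient set to (possibly new) data.
## coefs: mode, reference, alpha/sigma2 (vector in grand mode, batches x
## features in batchwise mode), beta, gamma_star, delta2_star.
apply_harmonization <- function(coefs, values, batch, covariates = NULL,
                                form = c("eq2", "literal")) {
  form <- match.arg(form)
  batch <- factor(as.character(batch))
  unseen <- setdiff(levels(batch), rownames(coefs$gamma_star))
  if (length(unseen))
    stop("batch label(s) not seen at fit time: ",
         paste(unseen, collapse = ", "),
         "; ComBat cannot extrapolate to unseen batches", call. = FALSE)
  n <- nrow(values)
  G <- ncol(values)
  idx <- match(as.character(batch), rownames(coefs$gamma_star))
  batchwise <- identical(coefs$mode, "batchwise")

  cov_term <- if (!is.null(coefs$beta)) {
    if (is.null(covariates))
      stop("model was fit with covariates; supply 'covariates'", call. = FALSE)
    as.matrix(covariates) %*% coefs$beta
  } else 0

  ## location/scale removed on the way in
  if (batchwise) {
    std_mean <- coefs$alpha[idx, , drop = FALSE] + cov_term
    std_scale <- sqrt(coefs$sigma2)[idx, , drop = FALSE]
    adj_alpha <- coefs$alpha[coefs$reference, ]
    adj_sigma <- sqrt(coefs$sigma2[coefs$reference, ])
  } else {
    std_mean <- matrix(coefs$alpha, n, G, byrow = TRUE) + cov_term
    std_scale <- matrix(sqrt(coefs$sigma2), n, G, byrow = TRUE)
    adj_alpha <- coefs$alpha
    adj_sigma <- sqrt(coefs$sigma2)
  }
  ## location/scale restored on the way out (reference batch's in
  ## batchwise mode)
  adj_mean <- matrix(adj_alpha, n, G, byrow = TRUE) + cov_term
  adj_scale <- matrix(adj_sigma, n, G, byrow = TRUE)

  delta_i <- sqrt(coefs$delta2_star[idx, , drop = FALSE])
  gamma_i <- coefs$gamma_star[idx, , drop = FALSE]
  out <- if (form == "literal") {
    ## coefficients applied on the raw scale, as printed for the
    ## bootstrapped variants
    (values - adj_mean - gamma_i) / delta_i + adj_mean
  } else {
    (adj_scale / delta_i) * ((values - std_mean) / std_scale - gamma_i) +
      adj_mean
  }
  dimnames(out) <- dimnames(values)
  out
}

#' Harmonize a multicenter feature table with the ComBat family
#'
#' Fits the empirical-Bayes location-scale batch-effect model and removes
#' the estimated per-batch effects. Four variants are available:
#'
#' * `"combat"` - classic ComBat: features are recentered on the pooled
#'   (grand) location and scale;
#' * `"m-combat"` - reference-anchored: all batches are mapped onto the
#'   mean and spread of a chosen reference batch, which itself is left
#'   (essentially) unchanged;
#' * `"b-combat"` / `"bm-combat"` - the same two geometries with all
#'   coefficients stabilized by stratified bootstrap resampling and
#'   Monte-Carlo averaging over `n_boot` refits.
#'
#' @param values numeric samples-by-features matrix (or a
#'   `"feature_table"` from [read_feature_table()], in which case `batch`,
#'   `covariates` and `outcome` default to its components).
#' @param batch per-sample batch labels; nominal categories.
#' @param covariates optional numeric covariate matrix whose (biological)
#'   effect is estimated jointly and preserved.
#' @param variant one of `"combat"`, `"m-combat"`, `"b-combat"`,
#'   `"bm-combat"`.
#' @param prior empirical-Bayes prior: `"nonparametric"` (default),
#'   `"parametric"`, or `"none"` (raw estimates, diagnostic mode).
#' @param reference reference batch label for the M variants; defaults to
#'   the largest batch.
#' @param n_boot number of bootstrap resamples for the B variants.
#' @param seed integer seed; required for the B variants.
#' @param bootstrap_mode `"case"` (stratified case resampling, default) or
#'   `"parametric"` (model-based resampling).
#' @param bootstrap_form `"eq2"` (default) inserts the bootstrap-averaged
#'   coefficients into the standard adjustment form; `"literal"` applies
#'   them on the raw scale.
#' @param drop_degenerate drop (with a message) features with zero
#'   within-batch variance instead of raising an error.
#' @param outcome optional outcome vector, accepted only so the fit can
#'   refuse outcome leakage into the covariates.
#' @return An object of class `"radharmony"`; see [fitted.radharmony()],
#'   [coef.radharmony()], [predict.radharmony()].
#' @examples
#' toy <- matrix(c(1, 2, 3, 11, 12, 13), ncol = 1,
#'               dimnames = list(paste0("s", 1:6), "f1"))
#' fit <- harmonize(toy, rep(c("A", "B"), each = 3), prior = "none")
#' colMeans(fitted(fit))  # batch means aligned on the grand mean
#' @export
harmonize <- function(values, batch = NULL, covariates = NULL,
                      variant = c("combat", "m-combat", "b-combat",
                                  "bm-combat"),
                      prior = c("nonparametric", "parametric", "none"),
                      reference = NULL, n_boot = 1000L, seed = NULL,
                      bootstrap_mode = c("case", "parametric"),
                      bootstrap_form = c("eq2", "literal"),
                      drop_degenerate = FALSE, outcome = NULL) {
  variant <- match.arg(variant)
  prior <- match.arg(prior)
  bootstrap_mode <- match.arg(bootstrap_mode)
  bootstrap_form <- match.arg(bootstrap_form)
  cl <- match.call()

  if (inherits(values, "feature_table")) {
    if (is.null(batch)) batch <- values$batch
    if (is.null(covariates)) covariates <- values$covariates
    if (is.null(outcome)) outcome <- values$outcome
    values <- values$values
  }
  if (is.null(batch)) stop("'batch' labels are required", call. = FALSE)
  values <- check_values(values)
  bootstrapped <- variant %in% c("b-combat", "bm-combat")
  batch <- check_batch(batch, nrow(values),
                       min_per_batch = if (bootstrapped) 3L else 2L)
  covariates <- check_covariates(covariates, nrow(values))

  if (!is.null(outcome) && !is.null(covariates)) {
    y <- as.numeric(outcome)
    leak <- apply(covariates, 2L, function(x)
      isTRUE(all.equal(as.numeric(x), y)) ||
        (stats::sd(x) > 0 && stats::sd(y) > 0 && abs(stats::cor(x, y)) > 0.999))
    if (any(leak))
      stop("covariate(s) ", paste(colnames(covariates)[leak], collapse = ", "),
           " duplicate the outcome; the outcome must never be passed as a ",
           "covariate", call. = FALSE)
  }

  mode <- if (variant %in% c("m-combat", "bm-combat")) "batchwise" else "grand"
  if (mode == "batchwise") {
    if (is.null(reference)) {
      tab <- table(batch)
      reference <- names(tab)[which.max(tab)]
      message("using largest batch '", reference, "' as reference")
    }
    reference <- as.character(reference)
    if (!reference %in% levels(batch))
      stop("reference batch '", reference, "' not among batch labels",
           call. = FALSE)
  } else reference <- NULL

  dropped <- character(0)
  bad <- degenerate_features(values, batch)
  if (length(bad)) {
    if (!drop_degenerate)
      stop("feature(s) with zero within-batch variance: ",
           paste(colnames(values)[bad], collapse = ", "),
           "; set drop_degenerate = TRUE to drop them", call. = FALSE)
    dropped <- colnames(values)[bad]
    message("dropping ", length(bad), " degenerate feature(s): ",
            paste(dropped, collapse = ", "))
    values <- values[, -bad, drop = FALSE]
  }

  if (bootstrapped) {
    if (is.null(seed))
      stop("variant '", variant, "' requires an integer 'seed'", call. = FALSE)
    bf <- bootstrap_fit(values, batch, covariates, mode,
                        B = n_boot, seed = seed, prior = prior,
                        bootstrap_mode = bootstrap_mode)
    coefs <- list(mode = mode, reference = reference,
                  alpha = bf$alpha, beta = bf$beta, sigma2 = bf$sigma2,
                  gamma_star = bf$gamma_star, delta2_star = bf$delta2_star)
    raw <- list(gamma_hat = bf$point_fit$effects$gamma_hat,
                delta2_hat = bf$point_fit$effects$delta2_hat)
    hyper <- bf$point_fit$effects$hyper
    bootstrap <- list(B = bf$B, seed = bf$seed, mode = bf$bootstrap_mode,
                      n_redraws = bf$n_redraws)
    corrected <- apply_harmonization(coefs, values, batch, covariates,
                                     form = if (bootstrap_form == "literal")
                                       "literal" else "eq2")
  } else {
    fit <- combat_single_fit(values, batch, covariates, mode, prior)
    coefs <- list(mode = mode, reference = reference,
                  alpha = fit$std$alpha, beta = fit$std$beta,
                  sigma2 = fit$std$sigma2,
                  gamma_star = fit$effects$gamma_star,
                  delta2_star = fit$effects$delta2_star)
    raw <- list(gamma_hat = fit$effects$gamma_hat,
                delta2_hat = fit$effects$delta2_hat)
    hyper <- fit$effects$hyper
    bootstrap <- NULL
    corrected <- adjust_data(fit$std$z, fit$std, fit$effects, batch,
                             covariates, reference = reference)
  }

  structure(list(corrected = corrected, original = values,
                 variant = variant, prior = prior, mode = mode,
                 reference = reference, coefficients = coefs, raw = raw,
                 hyper = hyper, bootstrap = bootstrap,
                 bootstrap_form = if (bootstrapped) bootstrap_form,
                 batch = batch, n_i = as.vector(table(batch)),
                 dropped_features = dropped, call = cl),
            class = "radharmony")
}

#' @export
print.radharmony <- function(x, ...) {
  cat(sprintf("ComBat harmonization fit (variant: %s, prior: %s)\n",
              x$variant, x$prior))
  cat(sprintf("  %d samples x %d features, %d batches (%s)\n",
              nrow(x$corrected), ncol(x$corrected), nlevels(x$batch),
              paste(sprintf("%s: %d", levels(x$batch), x$n_i),
                    collapse = ", ")))
  if (!is.null(x$reference)) cat("  reference batch:", x$reference, "\n")
  if (!is.null(x$bootstrap))
    cat(sprintf("  bootstrap: B = %d (%s resampling, seed %d, %d redraws)\n",
                x$bootstrap$B, x$bootstrap$mode, x$bootstrap$seed,
                x$bootstrap$n_redraws))
  if (length(x$dropped_features))
    cat("  dropped degenerate features:", length(x$dropped_features), "\n")
  invisible(x)
}

#' Summarize a harmonization fit
#'
#' Reports per-batch sample counts, prior hyperparameters, and the
#' evaluation battery before/after harmonization: fraction of features
#' with significant across-batch ANOVA differences and the aggregate
#' coefficient of variation.
#'
#' @param object a `"radharmony"` fit.
#' @param alpha significance threshold for the per-feature ANOVA.
#' @param ... unused.
#' @export
summary.radharmony <- function(object, alpha = 0.01, ...) {
  pre <- per_feature_anova(object$original, object$batch, alpha = alpha)
  post <- per_feature_anova(object$corrected, object$batch, alpha = alpha)
  out <- list(fit = object, alpha = alpha,
              frac_significant_pre = pre$frac_significant,
              frac_significant_post = post$frac_significant,
              n_significant_pre = sum(pre$p < alpha),
              n_significant_post = sum(post$p < alpha),
              cov_pre = aggregate_cov(object$original),
              cov_post = aggregate_cov(object$corrected))
  class(out) <- "summary.radharmony"
  out
}

#' @export
print.summary.radharmony <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  ANOVA across batches (alpha = %g): %d/%d significant before, %d after\n",
              x$alpha, x$n_significant_pre, ncol(x$fit$corrected),
              x$n_significant_post))
  cat(sprintf("  aggregate COV: %.1f before, %.1f after\n",
              x$cov_pre, x$cov_post))
  if (identical(x$fit$mode, "batchwise")) {
    cat("  prior: degenerate by construction (batchwise effects are exactly 0/1)\n")
  } else if (!is.null(x$fit$hyper)) {
    h <- x$fit$hyper
    cat("  prior hyperparameters per batch:\n")
    for (i in seq_along(h$gamma_bar))
      cat(sprintf("    %s: gamma_bar = %.3g, t2 = %.3g, IG(a = %.3g, b = %.3g)\n",
                  levels(x$fit$batch)[i], h$gamma_bar[i], h$t2[i],
                  h$a_prior[i], h$b_prior[i]))
  }
  invisible(x)
}

#' Extract batch-effect coefficients
#'
#' @param object a `"radharmony"` fit.
#' @param ... unused.
#' @return A list with the shrunken effects `gamma` and `delta2`
#'   (batches x features), the location `alpha` and scale `sigma2`
#'   (per-feature vectors for the grand-mode variants, batches-by-features
#'   matrices for the reference-anchored ones), and covariate coefficients
#'   `beta` (or `NULL`).
#' @export
coef.radharmony <- function(object, ...) {
  with(object$coefficients,
       list(gamma = gamma_star, delta2 = delta2_star,
            alpha = alpha, sigma2 = sigma2, beta = beta))
}

#' @export
fitted.radharmony <- function(object, ...) object$corrected

#' @export
residuals.radharmony <- function(object, ...)
  object$original - object$corrected

#' Re-apply a fitted harmonization transform
#'
#' Applies the stored coefficients to new rows from batches seen at fit
#' time (exact re-application to the same cohort). Samples from unseen
#' batches are refused: the model cannot extrapolate to a batch whose
#' effects were never estimated.
#'
#' @param object a `"radharmony"` fit.
#' @param newdata numeric samples-by-features matrix with the fitted
#'   feature set.
#' @param batch batch labels for the new rows (must be seen at fit time).
#' @param covariates covariates for the new rows if the model used them.
#' @param ... unused.
#' @export
predict.radharmony <- function(object, newdata, batch, covariates = NULL,
                               ...) {
  newdata <- as.matrix(newdata)
  feats <- colnames(object$corrected)
  if (!is.null(colnames(newdata))) {
    miss <- setdiff(feats, colnames(newdata))
    if (length(miss))
      stop("newdata is missing feature(s): ",
           paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
    newdata <- newdata[, feats, drop = FALSE]
  } else if (ncol(newdata) != length(feats))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(feats), call. = FALSE)
  form <- if (identical(object$bootstrap_form, "literal")) "literal" else "eq2"
  apply_harmonization(object$coefficients, newdata, batch, covariates, form)
}

#' Plot a harmonization fit
#'
#' Side-by-side scatter of the top two principal components before and
#' after harmonization, colored by batch.
#'
#' @param x a `"radharmony"` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.radharmony <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  cols <- as.integer(x$batch)
  for (panel in c("before", "after")) {
    v <- if (panel == "before") x$original else x$corrected
    p <- pca_top2(v)
    graphics::plot(p$scores, col = cols, pch = 19,
                   xlab = sprintf("PC1 (%.0f%%)", 100 * p$explained[1]),
                   ylab = sprintf("PC2 (%.0f%%)", 100 * p$explained[2]),
                   main = panel, ...)
  }
  graphics::legend("topright", legend = levels(x$batch), col =
                     seq_len(nlevels(x$batch)), pch = 19, cex = 0.8)
  invisible(x)
}

#' Serialize a harmonization model to JSON for audit
#'
#' Writes the variant, prior mode, hyperparameters and all per-batch
#' coefficient arrays; [read_model_json()] restores an object usable with
#' [predict.radharmony()] for exact re-application to the same cohort.
#'
#' @param object a `"radharmony"` fit.
#' @param path output path.
#' @export
write_model_json <- function(object, path) {
  stopifnot(inherits(object, "radharmony"))
  co <- object$coefficients
  payload <- list(
    package = "radharmony", variant = object$variant, prior = object$prior,
    mode = object$mode, reference = object$reference,
    batch_levels = levels(object$batch), n_i = object$n_i,
    feature_names = colnames(object$corrected),
    alpha = unname(co$alpha), sigma2 = unname(co$sigma2),
    beta = if (!is.null(co$beta)) unname(co$beta),
    covariate_names = if (!is.null(co$beta)) rownames(co$beta),
    gamma_star = unname(co$gamma_star), delta2_star = unname(co$delta2_star),
    hyper = object$hyper, bootstrap = object$bootstrap,
    bootstrap_form = object$bootstrap_form,
    dropped_features = object$dropped_features)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @param path path to a JSON file written by [write_model_json()].
#' @export
read_model_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  lv <- m$batch_levels
  feats <- m$feature_names
  shape <- function(x, rn) {
    if (!is.matrix(x)) x <- matrix(unlist(x), nrow = length(rn), byrow = TRUE)
    dimnames(x) <- list(rn, feats)
    x
  }
  gamma_star <- shape(m$gamma_star, lv)
  delta2_star <- shape(m$delta2_star, lv)
  beta <- if (!is.null(m$beta)) shape(m$beta, m$covariate_names)
  batchwise <- identical(m$mode, "batchwise")
  alpha <- if (batchwise) shape(m$alpha, lv) else
    stats::setNames(unlist(m$alpha), feats)
  sigma2 <- if (batchwise) shape(m$sigma2, lv) else
    stats::setNames(unlist(m$sigma2), feats)
  structure(list(corrected = matrix(numeric(0), 0, length(feats),
                                    dimnames = list(NULL, feats)),
                 variant = m$variant, prior = m$prior, mode = m$mode,
                 reference = m$reference,
                 coefficients = list(
                   mode = m$mode, reference = m$reference,
                   alpha = alpha, sigma2 = sigma2,
                   beta = beta, gamma_star = gamma_star,
                   delta2_star = delta2_star),
                 hyper = m$hyper, bootstrap = m$bootstrap,
                 bootstrap_form = m$bootstrap_form,
                 batch = factor(character(0), levels = lv),
                 n_i = m$n_i, dropped_features = m$dropped_features,
                 call = NULL),
            class = "radharmony")
}
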