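## Synthetic multicenter cohorts with known ground-truth batch effects.
##
## The generator is the exact generative inverse of the harmonization
## model: Y_ijg = alpha_g + X_ij beta_g + sigma_g * (gamma_ig +
## delta_ig * eps_ijg) with standard-normal eps, so every estimator in the
## package can be validated against known truth. The binary outcome is
## drawn from a logistic model on the PRE-batch-effect biology (eps), so
## biology is batch-independent by construction.

#' Specify a synthetic multicenter cohort
#'
#' Batch effects are injected in units of each feature's biological scale
#' `sigma_g`, so effect sizes are comparable across features. Defaults
#' emulate a mid-sized multicenter radiomic study: 3 batches, 150
#' features, additive shifts of 1.5-2.5 SD with random sign, scale
#' distortions of +/- 20%, and a 25% event rate driven by 5 informative
#' features.
#'
#' @param n_batches number of batches `I`.
#' @param batch_sizes integer vector of per-batch sample counts.
#' @param n_features number of features `G`.
#' @param base_mean_range range for the per-feature biological means
#'   `alpha_g` (uniform draw).
#' @param base_scale_range range for the biological scales `sigma_g`.
#' @param gamma_range range for the magnitude of the per-batch additive
#'   shifts, in `sigma_g` units; `c(0, 0)` gives the no-batch-effect null.
#' @param gamma_sign `"random"` (each batch-feature shift gets an
#'   independent random sign) or `"positive"`.
#' @param delta_range range for the per-batch multiplicative scale
#'   factors (must be positive).
#' @param n_covariates number of standard-normal covariates with effects
#'   drawn from `beta_range`.
#' @param beta_range range for covariate effect sizes.
#' @param n_informative number of features carrying outcome signal.
#' @param outcome_effect total effect size of the informative features on
#'   the outcome logit (SD of the linear predictor).
#' @param event_rate target marginal event rate, in (0, 1).
#' @param confounded_outcome inject a per-batch offset on the outcome
#'   logit (to exercise the outcome-confounding check); default `FALSE`.
#' @param correlation optional equicorrelation of the biological noise
#'   across features, in `[0, 1)`.
#' @param seed default seed used by [generate_synthetic()].
#' @return A list of class `"synth_spec"`.
#' @export
synth_spec <- function(n_batches = 3L, batch_sizes = c(60L, 50L, 40L),
                       n_features = 150L,
                       base_mean_range = c(5, 50),
                       base_scale_range = c(0.5, 5),
                       gamma_range = c(1.5, 2.5), gamma_sign = "random",
                       delta_range = c(0.8, 1.2),
                       n_covariates = 0L, beta_range = c(0.5, 1),
                       n_informative = 5L, outcome_effect = 1.5,
                       event_rate = 0.25, confounded_outcome = FALSE,
                       correlation = 0, seed = NULL) {
  if (length(batch_sizes) != n_batches)
    stop("'batch_sizes' must have length 'n_batches'", call. = FALSE)
  if (n_batches < 1L || any(batch_sizes < 2L))
    stop("need >= 1 batch with >= 2 samples each", call. = FALSE)
  if (n_features < 1L) stop("need >= 1 feature", call. = FALSE)
  if (any(delta_range <= 0)) stop("'delta_range' must be positive", call. = FALSE)
  if (event_rate <= 0 || event_rate >= 1)
    stop("'event_rate' must be in (0, 1)", call. = FALSE)
  if (correlation < 0 || correlation >= 1)
    stop("'correlation' must be in [0, 1)", call. = FALSE)
  if (n_informative > n_features)
    stop("'n_informative' exceeds 'n_features'", call. = FALSE)
  gamma_sign <- match.arg(gamma_sign, c("random", "positive"))
  structure(as.list(environment()), class = "synth_spec")
}

#' Generate a synthetic multicenter cohort
#'
#' @param spec a [synth_spec()].
#' @param seed integer seed; defaults to `spec$seed`. All randomness flows
#'   from this one seed, so two calls with the same seed are identical.
#' @return A list with `values` (samples x features), `batch` (factor),
#'   `covariates` (matrix or `NULL`), `outcome` (0/1 vector), and `truth`
#'   (the injected `alpha`, `sigma`, `gamma`, `delta`, covariate effects,
#'   informative feature indices and outcome coefficients).
#' @export
generate_synthetic <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synth_spec"))
  if (is.null(seed))
    stop("a 'seed' is required (in the spec or as argument)", call. = FALSE)
  set.seed(as.integer(seed))

  I <- spec$n_batches
  G <- spec$n_features
  n_i <- spec$batch_sizes
  n <- sum(n_i)
  batch <- factor(rep(paste0("batch", seq_len(I)), n_i))

  alpha <- stats::runif(G, spec$base_mean_range[1], spec$base_mean_range[2])
  sigma <- stats::runif(G, spec$base_scale_range[1], spec$base_scale_range[2])
  gamma <- matrix(stats::runif(I * G, spec$gamma_range[1], spec$gamma_range[2]),
                  I, G)
  if (spec$gamma_sign == "random") {
    ## signs are drawn per feature from the NON-constant patterns across
    ## batches: a shift common to every batch is absorbed into alpha_g and
    ## is not an identifiable batch effect, so injected "batch effects"
    ## must differ somewhere between batches
    signs <- if (I == 1L) {
      matrix(sample(c(-1, 1), G, replace = TRUE), 1L, G)
    } else {
      patterns <- as.matrix(expand.grid(rep(list(c(-1, 1)), I)))
      keep <- rowSums(patterns == 1L) %in% seq_len(I - 1L)
      patterns <- patterns[keep, , drop = FALSE]
      t(patterns[sample.int(nrow(patterns), G, replace = TRUE), ,
                 drop = FALSE])
    }
    gamma <- gamma * signs
  }
  delta <- matrix(stats::runif(I * G, spec$delta_range[1], spec$delta_range[2]),
                  I, G)
  lv <- levels(batch)
  dimnames(gamma) <- dimnames(delta) <-
    list(lv, paste0("feature_", seq_len(G)))

  covariates <- NULL
  beta_cov <- NULL
  if (spec$n_covariates > 0L) {
    covariates <- matrix(stats::rnorm(n * spec$n_covariates), n,
                         spec$n_covariates,
                         dimnames = list(NULL, paste0("x", seq_len(spec$n_covariates))))
    beta_cov <- matrix(stats::runif(spec$n_covariates * G, spec$beta_range[1],
                                    spec$beta_range[2]),
                       spec$n_covariates, G)
  }

  eps <- matrix(stats::rnorm(n * G), n, G)
  if (spec$correlation > 0) {
    f <- stats::rnorm(n)
    eps <- sqrt(spec$correlation) * f + sqrt(1 - spec$correlation) * eps
  }

  ib <- as.integer(batch)
  values <- matrix(alpha, n, G, byrow = TRUE) +
    matrix(sigma, n, G, byrow = TRUE) *
    (gamma[ib, , drop = FALSE] + delta[ib, , drop = FALSE] * eps)
  if (!is.null(covariates)) values <- values + covariates %*% beta_cov
  dimnames(values) <- list(sprintf("sample_%03d", seq_len(n)),
                           paste0("feature_", seq_len(G)))

  informative <- seq_len(spec$n_informative)
  w <- if (spec$n_informative > 0)
    rep(spec$outcome_effect / sqrt(spec$n_informative), spec$n_informative)
  else numeric(0)
  eta <- if (spec$n_informative > 0)
    as.vector(eps[, informative, drop = FALSE] %*% w)
  else rep(0, n)
  if (isTRUE(spec$confounded_outcome))
    eta <- eta + seq(-1, 1, length.out = I)[ib]
  ## calibrate the intercept so the realized-linear-predictor event rate
  ## matches the requested one
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta)) - spec$event_rate,
                       c(-30, 30))$root
  outcome <- stats::rbinom(n, 1L, stats::plogis(b0 + eta))

  list(values = values, batch = batch, covariates = covariates,
       outcome = outcome,
       truth = list(alpha = alpha, sigma = sigma, gamma = gamma,
                    delta = delta, beta_covariates = beta_cov,
                    informative = informative, outcome_weights = w,
                    outcome_intercept = b0, seed = as.integer(seed)))
}

#' Cohort presets mirroring the two published multicenter studies
#'
#' `lacc_like_preset()` follows the cervical-cancer cohort shape: 3
#' centers of 119, 50 and 28 patients (197 total), 173 features (79
#' morphological/intensity + 94 textural), 34% event rate.
#' `lalc_like_preset()` follows the laryngeal-cancer cohort shape after
#' cluster discovery: 2 clusters of 60 and 38 patients, 173 features, 15%
#' event rate.
#'
#' @param ... overrides passed to [synth_spec()].
#' @return A [synth_spec()].
#' @export
lacc_like_preset <- function(...) {
  args <- list(n_batches = 3L, batch_sizes = c(119L, 50L, 28L),
               n_features = 173L, event_rate = 0.34)
  do.call(synth_spec, utils::modifyList(args, list(...)))
}

#' @rdname lacc_like_preset
#' @export
lalc_like_preset <- function(...) {
  args <- list(n_batches = 2L, batch_sizes = c(60L, 38L),
               n_features = 173L, event_rate = 0.15)
  do.call(synth_spec, utils::modifyList(args, list(...)))
}
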