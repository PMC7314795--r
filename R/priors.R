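## Empirical-Bayes priors and shrinkage for per-batch location-scale effects.
##
## The location effects gamma_ig get a Normal prior, the scale effects
## delta2_ig an Inverse-Gamma prior, both per batch with hyperparameters
## pooled across features by the method of moments. Shrinkage is either the
## iterative parametric posterior-mean solution under Normal/Inverse-Gamma
## conjugacy, or the nonparametric weighted-likelihood posterior
## integration over the other features' raw estimates.

moments_hyperparameters <- function(gamma_hat, delta2_hat) {
  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1L, stats::var)
  m <- rowMeans(delta2_hat)
  s2 <- apply(delta2_hat, 1L, stats::var)
  a_prior <- (2 * s2 + m^2) / s2
  b_prior <- (m * s2 + m^3) / s2
  if (any(is.finite(a_prior) & a_prior <= 1))
    warning("Inverse-Gamma prior with shape <= 1 (infinite prior mean) for batch(es): ",
            paste(rownames(gamma_hat)[a_prior <= 1], collapse = ", "),
            call. = FALSE)
  list(gamma_bar = gamma_bar, t2 = t2, a_prior = a_prior, b_prior = b_prior)
}

## Iterative parametric EB solution for one batch.
## zi: samples x features for that batch; conv on the relative change,
## matching the classic ComBat iteration.
it_solve <- function(zi, g_hat, d_hat, g_bar, t2, a, b,
                     conv = 1e-4, max_iter = 100L) {
  n <- nrow(zi)
  if (!is.finite(a) || !is.finite(b)) {
    ## zero across-feature spread of delta2_hat: the scale prior is a
    ## point mass, so the posterior scale equals the raw estimate and the
    ## location posterior mean is available in closed form
    g_new <- (t2 * n * g_hat + d_hat * g_bar) / (t2 * n + d_hat)
    return(list(gamma_star = g_new, delta2_star = d_hat, n_iter = 0L))
  }
  g_old <- g_hat
  d_old <- d_hat
  for (iter in seq_len(max_iter)) {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- colSums((zi - matrix(g_new, n, length(g_new), byrow = TRUE))^2)
    d_new <- (0.5 * sum2 + b) / (n / 2 + a - 1)
    change <- max(abs(g_new - g_old) / g_old, abs(d_new - d_old) / d_old)
    g_old <- g_new
    d_old <- d_new
    if (change <= conv)
      return(list(gamma_star = g_new, delta2_star = d_new, n_iter = iter))
  }
  stop(sprintf(paste0("parametric EB iteration did not converge after %d ",
                      "iterations (last relative change %.3g)"),
               max_iter, change), call. = FALSE)
}

## Nonparametric posterior integration for one batch, via sufficient
## statistics: the Normal likelihood of batch data under (gamma_g',
## delta2_g') depends on the data only through n, sum(z) and sum(z^2), so
## the feature-by-feature weight matrix is computed in closed form and in
## log space (numerically stable where the naive per-sample product
## underflows).
np_solve <- function(zi, g_hat, d_hat) {
  n <- nrow(zi)
  G <- length(g_hat)
  s1 <- colSums(zi)
  s2 <- colSums(zi^2)
  ## loglik[g, g']: likelihood of feature g's batch data under feature g's
  ## raw estimates from feature g'
  quad <- outer(s2, 1 / (2 * d_hat)) - outer(s1, g_hat / d_hat) +
    matrix(n * g_hat^2 / (2 * d_hat), G, G, byrow = TRUE)
  loglik <- -matrix((n / 2) * log(2 * pi * d_hat), G, G, byrow = TRUE) - quad
  diag(loglik) <- -Inf  # each feature integrates over the *other* features
  mx <- apply(loglik, 1L, max)
  w <- exp(loglik - mx)
  wsum <- rowSums(w)
  list(gamma_star = as.vector(w %*% g_hat) / wsum,
       delta2_star = as.vector(w %*% d_hat) / wsum)
}

#' Fit empirical-Bayes priors and shrink batch effects
#'
#' Estimates per-batch prior hyperparameters by the method of moments
#' (pooling across features) and replaces the raw per-batch effects with
#' their empirical-Bayes posterior means. With `prior = "none"` the raw
#' estimates pass through unchanged (diagnostic/oracle mode).
#'
#' @param effects raw estimates from [estimate_batch_effects()].
#' @param prior `"nonparametric"` (default), `"parametric"`, or `"none"`.
#' @param z standardized matrix (required for the two shrinkage modes).
#' @param batch per-sample batch labels (required for shrinkage).
#' @param conv convergence tolerance on the relative coefficient change of
#'   the parametric iteration.
#' @param max_iter iteration cap for the parametric solution.
#' @return A list with `gamma_star`, `delta2_star` (batches x features),
#'   the raw `gamma_hat`/`delta2_hat`, `hyper` (prior hyperparameters, or
#'   `NULL` for `prior = "none"`), and `prior`.
#' @export
fit_priors_and_shrink <- function(effects, prior = c("nonparametric",
                                                     "parametric", "none"),
                                  z = NULL, batch = NULL,
                                  conv = 1e-4, max_iter = 100L) {
  prior <- match.arg(prior)
  gamma_hat <- effects$gamma_hat
  delta2_hat <- effects$delta2_hat

  if (prior == "none")
    return(list(gamma_star = gamma_hat, delta2_star = delta2_hat,
                gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                hyper = NULL, prior = prior))

  if (ncol(gamma_hat) < 2L)
    stop("empirical-Bayes shrinkage pools across features; need >= 2 features",
         call. = FALSE)
  if (is.null(z) || is.null(batch))
    stop("'z' and 'batch' are required for prior = '", prior, "'",
         call. = FALSE)
  batch <- factor(as.character(batch))
  hyper <- moments_hyperparameters(gamma_hat, delta2_hat)

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  n_iter <- integer(nrow(gamma_hat))
  for (i in seq_len(nrow(gamma_hat))) {
    zi <- z[batch == rownames(gamma_hat)[i], , drop = FALSE]
    if (prior == "parametric") {
      sol <- it_solve(zi, gamma_hat[i, ], delta2_hat[i, ],
                      hyper$gamma_bar[i], hyper$t2[i],
                      hyper$a_prior[i], hyper$b_prior[i], conv, max_iter)
      n_iter[i] <- sol$n_iter
    } else {
      sol <- np_solve(zi, gamma_hat[i, ], delta2_hat[i, ])
    }
    gamma_star[i, ] <- sol$gamma_star
    delta2_star[i, ] <- sol$delta2_star
  }

  list(gamma_star = gamma_star, delta2_star = delta2_star,
       gamma_hat = gamma_hat, delta2_hat = delta2_hat,
       hyper = hyper, prior = prior, n_iter = n_iter)
}
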