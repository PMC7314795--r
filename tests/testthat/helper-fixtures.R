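# Shared fixtures, all built in code.

# the two-batch worked example: A = {1,2,3}, B = {11,12,13}, one feature
toy_ab <- function() {
  list(values = matrix(c(1, 2, 3, 11, 12, 13), ncol = 1,
                       dimnames = list(paste0("s", 1:6), "f1")),
       batch = factor(rep(c("A", "B"), each = 3)))
}

# well-separated Gaussian blobs in G dimensions
make_blobs <- function(centers, n_per, sd = 1, G = 2, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(centers), function(i)
    matrix(stats::rnorm(n_per * G, mean = centers[i], sd = sd), n_per, G)))
  dimnames(x) <- list(paste0("s", seq_len(nrow(x))),
                      paste0("f", seq_len(G)))
  list(values = x, labels = factor(rep(seq_along(centers), each = n_per)))
}

# small seeded multicenter cohort for engine tests
small_cohort <- function(seed = 7, n_features = 40,
                         batch_sizes = c(12L, 15L, 10L), ...) {
  generate_synthetic(synth_spec(n_batches = length(batch_sizes),
                                batch_sizes = batch_sizes,
                                n_features = n_features, seed = seed, ...))
}

# closed-form oracle for prior="none" harmonization, written directly from
# the location-scale definition (independent of the package's code path):
# per-batch standardize, then rescale to the pooled (or reference)
# location and scale.  Conventions: pooled sigma^2 = RSS/n (population),
# within-batch sd with n-1; reference sigma with n_r - 1.
oracle_none <- function(values, batch, reference = NULL) {
  batch <- factor(as.character(batch))
  out <- values
  batch_means <- apply(values, 2, function(v) tapply(v, batch, mean))
  if (is.null(dim(batch_means)))
    batch_means <- matrix(batch_means, nrow = nlevels(batch))
  for (g in seq_len(ncol(values))) {
    m_i <- tapply(values[, g], batch, mean)
    s_i <- tapply(values[, g], batch, sd)
    if (is.null(reference)) {
      n_i <- as.vector(table(batch))
      alpha <- sum(n_i * m_i) / sum(n_i)
      rss <- sum((values[, g] - m_i[as.character(batch)])^2)
      sigma <- sqrt(rss / nrow(values))
    } else {
      alpha <- m_i[[reference]]
      sigma <- s_i[[reference]]
    }
    for (l in levels(batch)) {
      r <- batch == l
      out[r, g] <- sigma * (values[r, g] - m_i[[l]]) / s_i[[l]] + alpha
    }
  }
  out
}

expect_within <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}
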