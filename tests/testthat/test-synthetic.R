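test_that("generation is bitwise reproducible from its seed", {
  sp <- synth_spec(seed = 42)
  d1 <- generate_synthetic(sp)
  d2 <- generate_synthetic(sp)
  expect_identical(d1$values, d2$values)
  expect_identical(d1$outcome, d2$outcome)
  expect_identical(d1$truth$gamma, d2$truth$gamma)
  d3 <- generate_synthetic(sp, seed = 43)
  expect_false(identical(d1$values, d3$values))
  expect_error(generate_synthetic(synth_spec()), "seed")
})

test_that("the null model (no batch effects) yields calibrated ANOVA rates", {
  set.seed(1)
  fracs <- vapply(1:10, function(s) {
    d <- generate_synthetic(synth_spec(gamma_range = c(0, 0),
                                       delta_range = c(1, 1),
                                       n_features = 100, seed = s))
    per_feature_anova(d$values, d$batch, alpha = 0.05)$frac_significant
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.05), 0.02)
})

test_that("injected shifts make most features batch-significant", {
  d <- generate_synthetic(synth_spec(seed = 0))
  a <- per_feature_anova(d$values, d$batch, alpha = 0.01)
  expect_gt(a$frac_significant, 0.9)
})

test_that("generated data obey the location-scale model exactly", {
  # prior="none" harmonization of model-true data leaves residual batch
  # effects at Monte-Carlo level only
  d <- generate_synthetic(synth_spec(batch_sizes = c(80L, 80L, 80L),
                                     n_features = 60, seed = 3))
  fit <- harmonize(d$values, d$batch, prior = "none")
  std <- fit_standardization(fitted(fit), d$batch, mode = "grand")
  eff <- estimate_batch_effects(std$z, d$batch)
  expect_lt(max(abs(eff$gamma_hat)), 1e-10)  # exactly removed

  # and the injected effects are recoverable from the raw data
  std0 <- fit_standardization(d$values, d$batch, mode = "grand")
  eff0 <- estimate_batch_effects(std0$z, d$batch)
  n_i <- as.vector(table(d$batch))
  g_centered <- sweep(d$truth$gamma, 2,
                      colSums(d$truth$gamma * n_i / sum(n_i)))
  conv <- sqrt(std0$sigma2) / d$truth$sigma
  expect_lt(mean(abs(sweep(eff0$gamma_hat, 2, conv, "*") - g_centered)), 0.1)
})

test_that("outcome is independent of batch unless confounding is requested", {
  set.seed(2)
  ps <- vapply(1:15, function(s) {
    d <- generate_synthetic(synth_spec(seed = s))
    suppressWarnings(chisq.test(table(d$batch, d$outcome))$p.value)
  }, numeric(1))
  # p-values behave like a uniform sample: no systematic association
  expect_gt(mean(ps), 0.25)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  d_conf <- generate_synthetic(synth_spec(confounded_outcome = TRUE,
                                          batch_sizes = c(150L, 150L, 150L),
                                          seed = 5))
  expect_lt(suppressWarnings(
    chisq.test(table(d_conf$batch, d_conf$outcome))$p.value), 0.01)
})

test_that("event rates track the requested rate and the presets' shapes", {
  set.seed(4)
  rates <- vapply(1:10, function(s)
    mean(generate_synthetic(synth_spec(batch_sizes = c(200L, 200L, 200L),
                                       seed = s))$outcome), numeric(1))
  expect_equal(mean(rates), 0.25, tolerance = 0.03)

  lacc <- lacc_like_preset(seed = 1)
  expect_equal(lacc$batch_sizes, c(119L, 50L, 28L))
  expect_equal(lacc$event_rate, 0.34)
  d <- generate_synthetic(lacc)
  expect_equal(dim(d$values), c(197L, 173L))

  lalc <- lalc_like_preset(seed = 1)
  expect_equal(lalc$batch_sizes, c(60L, 38L))
  expect_equal(lalc$event_rate, 0.15)
  expect_equal(lalc$n_features, 173L)
})

test_that("spec validation refuses impossible settings", {
  expect_error(synth_spec(n_batches = 2L, batch_sizes = c(10L, 10L, 10L)),
               "length")
  expect_error(synth_spec(delta_range = c(-1, 1)), "positive")
  expect_error(synth_spec(event_rate = 1.2), "event_rate")
  expect_error(synth_spec(n_informative = 500L), "informative")
  expect_error(synth_spec(correlation = 1), "correlation")
})

test_that("covariates and feature correlation enter the generative model", {
  d <- generate_synthetic(synth_spec(n_covariates = 2L,
                                     batch_sizes = c(100L, 100L, 100L),
                                     seed = 6))
  expect_equal(ncol(d$covariates), 2L)
  # regressing a feature on the covariate recovers a positive effect
  fit <- lm(d$values[, 1] ~ d$covariates + d$batch)
  expect_equal(unname(coef(fit)[2]), d$truth$beta_covariates[1, 1],
               tolerance = 0.5)

  d_cor <- generate_synthetic(synth_spec(correlation = 0.6,
                                         gamma_range = c(0, 0),
                                         delta_range = c(1, 1), seed = 7))
  z <- scale(d_cor$values)
  off <- cor(z)[upper.tri(diag(ncol(z)))]
  expect_equal(mean(off), 0.6, tolerance = 0.1)
})
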