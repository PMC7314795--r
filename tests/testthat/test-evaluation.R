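test_that("per-feature ANOVA matches hand-computed sums of squares", {
  # identical groups: no between-group variance, F = 0, p = 1
  v1 <- matrix(rep(c(1, 2, 3), 2), ncol = 1,
               dimnames = list(paste0("s", 1:6), "f"))
  lab <- factor(rep(c("A", "B"), each = 3))
  a1 <- per_feature_anova(v1, lab)
  expect_equal(unname(a1$p), 1)

  # {1,2,3} vs {11,12,13}: MSB = 150, MSW = 1, F = 150, p ~ 2.6e-4
  v2 <- matrix(c(1, 2, 3, 11, 12, 13), ncol = 1,
               dimnames = list(paste0("s", 1:6), "f"))
  a2 <- per_feature_anova(v2, lab)
  expect_equal(unname(a2$p), pf(150, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(unname(a2$p), 2.552e-4, tolerance = 1e-3)
  expect_equal(a2$frac_significant, 1)
})

test_that("ANOVA false-positive rate is calibrated at the null", {
  set.seed(101)
  hits <- 0L; total <- 0L
  for (s in 1:50) {
    v <- matrix(rnorm(40 * 20), 40, 20,
                dimnames = list(paste0("s", 1:40), paste0("f", 1:20)))
    lab <- factor(sample(rep(c("A", "B"), each = 20)))
    a <- per_feature_anova(v, lab, alpha = 0.01)
    hits <- hits + sum(a$p < 0.01); total <- total + 20L
  }
  # 1000 null tests at alpha = 0.01: Binomial(1000, .01), ~4.7 sd band
  expect_gt(hits / total, 0.001)
  expect_lt(hits / total, 0.025)
})

test_that("aggregate COV follows its definition", {
  one <- matrix(c(8, 10, 12), ncol = 1, dimnames = list(NULL, "f"))
  expect_equal(aggregate_cov(one), sd(c(8, 10, 12)) / 10 * 100)
  two <- cbind(a = c(8, 10, 12), b = c(3, 4, 5))
  expect_equal(aggregate_cov(two), 20 + 25)
  with_const <- cbind(two, flat = c(7, 7, 7))
  expect_equal(aggregate_cov(with_const), 45)  # constant contributes 0
  centered <- cbind(z = c(-1, 0, 1), a = c(8, 10, 12))
  expect_warning(cv <- aggregate_cov(centered), "zero-mean")
  expect_equal(cv, 20)
  expect_error(aggregate_cov(matrix(c(-1, 0, 1), ncol = 1,
                                    dimnames = list(NULL, "z"))),
               "zero mean")
})

test_that("top-2 PCA summary: rank-1 data, isotropy, duplication", {
  # points on a line: first component carries everything
  t_line <- seq(-2, 2, length.out = 10)
  line <- cbind(f1 = 3 * t_line, f2 = -1.5 * t_line)
  rownames(line) <- paste0("s", 1:10)
  p <- pca_top2(line, scale. = FALSE)
  expect_equal(p$explained[1], 1)
  expect_equal(p$explained[2], 0, tolerance = 1e-12)

  set.seed(33)
  iso <- matrix(rnorm(4000), 2000, 2,
                dimnames = list(NULL, c("f1", "f2")))
  rownames(iso) <- paste0("s", 1:2000)
  pi2 <- pca_top2(iso)
  expect_equal(unname(pi2$explained), c(0.5, 0.5), tolerance = 0.05)
  expect_gte(pi2$explained[1], pi2$explained[2])

  # hand eigen-decomposition oracle on the 2x2 correlation matrix
  set.seed(8)
  s <- rnorm(30)
  base <- cbind(f1 = s + rnorm(30, sd = 0.5), f2 = s + rnorm(30, sd = 0.5))
  rownames(base) <- paste0("s", 1:30)
  p1 <- pca_top2(base)
  ev <- eigen(cor(base))$values
  expect_equal(unname(p1$explained), ev / sum(ev), tolerance = 1e-10)

  # duplicated feature column: the dominant (shared-signal) component is
  # unchanged up to scaling of the scores
  dup <- cbind(base, f3 = base[, "f2"])
  p2 <- pca_top2(dup)
  expect_gt(abs(cor(p1$scores[, 1], p2$scores[, 1])), 0.99)
  expect_gt(p2$explained[1], p1$explained[1])  # duplicate reinforces PC1

  # deterministic sign: largest-magnitude loading positive
  expect_gt(p1$loadings[which.max(abs(p1$loadings[, 1])), 1], 0)
})

test_that("balanced accuracy and MCC match direct arithmetic", {
  cc <- function(tp, fp, tn, fn)
    structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
              class = "confusion_counts")
  expect_equal(balanced_accuracy(cc(5, 0, 5, 0)), 1)
  expect_equal(matthews_cc(cc(5, 0, 5, 0)), 1)
  expect_equal(balanced_accuracy(cc(3, 2, 4, 1)), (0.75 + 4 / 6) / 2)
  expect_equal(matthews_cc(cc(3, 2, 4, 1)), 10 / sqrt(600))
  expect_equal(matthews_cc(cc(1, 1, 1, 1)), 0)
  # all-positive predictions on balanced classes
  expect_equal(balanced_accuracy(cc(5, 5, 0, 0)), 0.5)
  expect_equal(matthews_cc(cc(5, 5, 0, 0)), 0)  # zero marginal convention
  expect_error(balanced_accuracy(cc(0, 2, 3, 0)), "positive")
})

test_that("BAcc and MCC are invariant under a full class swap", {
  set.seed(55)
  truth <- rbinom(60, 1, 0.3)
  pred <- ifelse(runif(60) < 0.75, truth, 1 - truth)
  c1 <- confusion_counts(truth, pred, positive = 1)
  c2 <- confusion_counts(1 - truth, 1 - pred, positive = 1)
  expect_equal(balanced_accuracy(c1), balanced_accuracy(c2))
  expect_equal(matthews_cc(c1), matthews_cc(c2))
})

test_that("the bundled report exposes the whole battery coherently", {
  d <- small_cohort(seed = 19, n_features = 25)
  rep_pre <- evaluate_harmonization(d$values, d$batch)
  rep_post <- evaluate_harmonization(fitted(harmonize(d$values, d$batch)),
                                     d$batch)
  expect_true(all(rep_pre$anova_p >= 0 & rep_pre$anova_p <= 1))
  expect_gt(rep_pre$frac_significant, rep_post$frac_significant)
  expect_gt(rep_pre$cov_aggregate, rep_post$cov_aggregate)
  expect_equal(dim(rep_pre$pca_scores), c(nrow(d$values), 2L))
  expect_length(rep_pre$per_label_summaries, nlevels(d$batch))
  expect_output(print(rep_pre), "aggregate COV")
})
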