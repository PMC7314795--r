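test_that("SMOTE synthesizes convex combinations of minority neighbors", {
  set.seed(3)
  x <- rbind(c(0, 0), c(2, 2), matrix(rnorm(20, 10), 10, 2))
  colnames(x) <- c("f1", "f2")
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  y <- c(1, 1, rep(0, 10))
  sm <- smote_oversample(x, y, k_neighbors = 1L, seed = 1)
  expect_equal(as.vector(table(sm$y)), c(10L, 10L))
  synth <- sm$x[grepl("^smote_", rownames(sm$x)), , drop = FALSE]
  # both minority points lie on the diagonal segment (0,0)-(2,2), so every
  # interpolation has equal coordinates within [0, 2]
  expect_within(synth[, 1], synth[, 2], 1e-12)
  expect_true(all(synth >= 0 & synth <= 2))
})

test_that("SMOTE contracts: balance, reproducibility, minimum class size", {
  set.seed(9)
  x <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("s", 1:30),
                                                c("f1", "f2")))
  y <- rep(c(0, 1), each = 15)
  expect_identical(smote_oversample(x, y)$x, x)  # balanced: unchanged

  y2 <- c(rep(0, 22), rep(1, 8))
  s1 <- smote_oversample(x, y2, seed = 4)
  s2 <- smote_oversample(x, y2, seed = 4)
  expect_identical(s1$x, s2$x)
  expect_equal(as.vector(table(s1$y)), c(22L, 22L))

  y3 <- c(rep(0, 27), rep(1, 3))
  expect_error(smote_oversample(x, y3, k_neighbors = 5L), "minority")
})

test_that("LASSO pipeline finds a strong predictor and stays at chance on noise", {
  set.seed(12)
  n <- 160
  x <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:20)))
  # outcome driven (strongly) by feature 7
  y <- as.integer(x[, 7] + rnorm(n, sd = 0.1) > 0)
  tr <- seq_len(100)
  res <- mr_lasso_pipeline(x[tr, ], y[tr], x[-tr, ], y[-tr], seed = 1)
  expect_true("f7" %in% res$selected)
  expect_gt(res$test[["bacc"]], 0.9)

  # pure-noise outcome: near-chance test performance across seeds
  baccs <- vapply(1:5, function(s) {
    set.seed(s)
    yn <- rbinom(n, 1, 0.5)
    mr_lasso_pipeline(x[tr, ], yn[tr], x[-tr, ], yn[-tr],
                      seed = s)$test[["bacc"]]
  }, numeric(1))
  expect_lt(abs(mean(baccs) - 0.5), 0.12)
})

test_that("correlated duplicates of a perfect predictor still get selected", {
  set.seed(14)
  n <- 100
  driver <- rnorm(n)
  x <- cbind(g1 = driver, g2 = driver, noise = matrix(rnorm(n * 5), n, 5))
  colnames(x) <- c("g1", "g2", paste0("n", 1:5))
  rownames(x) <- paste0("s", 1:n)
  y <- as.integer(driver > 0)
  res <- mr_lasso_pipeline(x[1:70, ], y[1:70], x[71:100, ], y[71:100],
                           seed = 2)
  expect_true(any(c("g1", "g2") %in% res$selected))
})

test_that("embedded RF selection recovers informative features", {
  cfg <- fs_config(n_trees = 60L, n_importance = 8L, n_val = 5L,
                   max_subset = 8L)
  hits <- vapply(1:4, function(s) {
    set.seed(s)
    n <- 90
    x <- matrix(rnorm(n * 30), n, 30,
                dimnames = list(paste0("s", 1:n), paste0("f", 1:30)))
    y <- factor(as.integer(rowMeans(x[, 1:5]) + rnorm(n, sd = 0.25) > 0))
    fs <- embedded_fs_rf(x, y, config = cfg, seed = s)
    sum(paste0("f", 1:5) %in% fs$subset)
  }, numeric(1))
  expect_gte(mean(hits), 3)  # most of the 5 informative features found

  # single feature: trivially chosen
  x1 <- matrix(rnorm(40), ncol = 1, dimnames = list(paste0("s", 1:40), "only"))
  y1 <- factor(rep(0:1, 20))
  fs1 <- embedded_fs_rf(x1, y1, config = cfg, seed = 1)
  expect_equal(fs1$subset, "only")
})

test_that("embedded SVM selection ranks a dominant feature first", {
  set.seed(17)
  n <- 80
  x <- cbind(sig = rnorm(n), matrix(rnorm(n * 10), n, 10))
  colnames(x) <- c("sig", paste0("f", 1:10))
  rownames(x) <- paste0("s", 1:n)
  y <- factor(as.integer(x[, "sig"] + rnorm(n, sd = 0.2) > 0))
  cfg <- fs_config(n_val = 5L, max_subset = 5L, svm_rank_folds = 5L)
  fs <- embedded_fs_svm(x, y, config = cfg, seed = 3)
  expect_equal(fs$ranking[1], "sig")
  expect_true("sig" %in% fs$subset)
  expect_true(fs$cost %in% cfg$svm_cost_grid)
})

test_that("forward selection error is non-increasing when duplicates enter", {
  set.seed(19)
  n <- 80
  driver <- rnorm(n)
  x <- cbind(a = driver, b = driver, c = rnorm(n))
  rownames(x) <- paste0("s", 1:n)
  y <- factor(as.integer(driver > 0))
  cfg <- fs_config(n_trees = 60L, n_importance = 6L, n_val = 8L,
                   max_subset = 3L)
  fs <- embedded_fs_rf(x, y, config = cfg, seed = 2)
  # the chosen prefix attains the global minimum of the validation error
  best <- length(fs$subset)
  expect_equal(fs$val_error[best], min(fs$val_error, na.rm = TRUE))
  expect_true(fs$ranking[1] %in% c("a", "b"))
})

test_that("the benchmark grid keeps the test set untouched and complete", {
  d <- generate_synthetic(synth_spec(batch_sizes = c(30L, 20L, 20L),
                                     n_features = 25, outcome_effect = 2,
                                     seed = 21))
  cfg <- benchmark_config(n_boot = 20L,
                          fs = fs_config(n_trees = 50L, n_importance = 4L,
                                         n_val = 3L, max_subset = 4L,
                                         svm_rank_folds = 3L))
  res <- run_benchmark(d$values, d$batch, d$outcome,
                       variants = c("untransformed", "combat"),
                       config = cfg, seed = 2)
  expect_s3_class(res, "benchmark_result")
  expect_setequal(unique(res$variant), c("untransformed", "combat"))
  expect_setequal(unique(res$pipeline), c("mr", "rf", "svm"))
  expect_setequal(unique(res$metric),
                  c("bacc", "mcc", "auc", "sensitivity", "specificity",
                    "accuracy"))
  v <- res$value[res$metric %in% c("bacc", "auc", "accuracy",
                                   "sensitivity", "specificity")]
  expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  expect_true(all(abs(res$value[res$metric == "mcc"]) <= 1))
  # the split is batch-defined: train = largest batch
  expect_equal(attr(res, "reference"), "batch1")
})

test_that("split contracts are enforced", {
  d <- generate_synthetic(synth_spec(n_batches = 2L,
                                     batch_sizes = c(30L, 20L), seed = 23,
                                     n_features = 10))
  one_class <- rep(0, nrow(d$values))
  expect_error(run_benchmark(d$values, d$batch, one_class), "outcome|class")
  expect_error(run_benchmark(d$values, factor(rep("A", nrow(d$values))),
                             d$outcome), "train and a test")
})
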