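## Imbalance-aware ML benchmark harness: SMOTE, three classification
## pipelines (LASSO-selected logistic regression; random forest and SVM
## with embedded nested-bootstrap feature selection), scored by balanced
## accuracy and Matthews correlation on a batch-defined held-out set,
## across untransformed and harmonized versions of the same table.

#' Synthetic minority oversampling (SMOTE)
#'
#' Balances a binary training set by synthesizing minority-class samples:
#' each synthetic sample is a convex combination `x + lambda * (x_nn - x)`
#' (`lambda ~ U[0, 1]`) of a random minority sample and one of its
#' `k_neighbors` nearest minority neighbors (Euclidean distance). An
#' already balanced input is returned unchanged. Training-fold use only:
#' the benchmark harness never lets synthetic samples touch a test set.
#'
#' @param x numeric samples-by-features matrix.
#' @param y binary outcome (0/1 or two-level factor) aligned with `x`.
#' @param k_neighbors number of minority nearest neighbors to draw from;
#'   the minority class must have at least `k_neighbors + 1` members.
#' @param seed optional integer seed.
#' @return A list with the augmented `x` and `y` (synthetic rows appended,
#'   named `smote_*`).
#' @export
smote_oversample <- function(x, y, k_neighbors = 5L, seed = NULL) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2L) stop("'y' must be binary", call. = FALSE)
  if (length(y) != nrow(x)) stop("'x' and 'y' not aligned", call. = FALSE)
  tab <- table(y)
  if (tab[1] == tab[2]) return(list(x = x, y = y))
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab)
  n_new <- abs(diff(as.vector(tab)))
  if (n_min < k_neighbors + 1L)
    stop("minority class has ", n_min, " members; need at least ",
         k_neighbors + 1L, " for k = ", k_neighbors, call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  xm <- x[y == minority, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- matrix(apply(d, 1L, function(r) order(r)[seq_len(k_neighbors)]),
               nrow = n_min, ncol = k_neighbors, byrow = TRUE)

  base <- sample.int(n_min, n_new, replace = TRUE)
  pick <- nn[cbind(base, sample.int(k_neighbors, n_new, replace = TRUE))]
  lambda <- stats::runif(n_new)
  synth <- xm[base, , drop = FALSE] +
    lambda * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  rownames(synth) <- paste0("smote_", seq_len(n_new))

  list(x = rbind(x, synth),
       y = factor(c(as.character(y), rep(minority, n_new)), levels = levels(y)))
}

## Confusion-derived metrics from class probabilities.
classifier_metrics <- function(truth, prob, threshold = 0.5) {
  truth <- factor(truth)
  positive <- levels(truth)[2]
  pred <- factor(ifelse(prob >= threshold, levels(truth)[2], levels(truth)[1]),
                 levels = levels(truth))
  cc <- confusion_counts(truth, pred, positive = positive)
  auc <- tryCatch(as.numeric(pROC::auc(pROC::roc(truth, prob, quiet = TRUE,
                                                 levels = levels(truth),
                                                 direction = "<"))),
                  error = function(e) NA_real_)
  c(bacc = balanced_accuracy(cc), mcc = matthews_cc(cc), auc = auc,
    sensitivity = cc$tp / (cc$tp + cc$fn),
    specificity = cc$tn / (cc$tn + cc$fp),
    accuracy = (cc$tp + cc$tn) / (cc$tp + cc$tn + cc$fp + cc$fn))
}

#' LASSO-selected multivariate logistic regression pipeline
#'
#' Fits the LASSO path with 10-fold cross-validation to choose the
#' penalty, then refits the nonzero-coefficient features in an
#' unpenalized logistic model and scores it on the test set. An empty
#' selected set falls back to an intercept-only model (flagged).
#'
#' @param x_train,y_train training features and binary outcome.
#' @param x_test,y_test held-out test set.
#' @param nfolds cross-validation folds for the penalty choice.
#' @param seed integer seed (fold assignment).
#' @return A list with `selected` (feature names), `fallback` flag, and
#'   `train`/`test` metric vectors (bacc, mcc, auc, sensitivity,
#'   specificity, accuracy).
#' @export
mr_lasso_pipeline <- function(x_train, y_train, x_test, y_test,
                              nfolds = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  y_train <- factor(y_train)
  y_test <- factor(y_test, levels = levels(y_train))
  if (nrow(x_train) < 10L) stop("need >= 10 training samples", call. = FALSE)
  cvfit <- glmnet::cv.glmnet(as.matrix(x_train), y_train,
                             family = "binomial", nfolds = nfolds)
  b <- as.matrix(stats::coef(cvfit, s = "lambda.min"))
  selected <- rownames(b)[-1][b[-1, 1] != 0]
  fallback <- length(selected) == 0L

  df_train <- data.frame(.y = y_train, check.names = FALSE)
  df_test <- data.frame(.y = y_test, check.names = FALSE)
  if (!fallback) {
    for (f in selected) {
      df_train[[f]] <- x_train[, f]
      df_test[[f]] <- x_test[, f]
    }
  }
  fit <- suppressWarnings(stats::glm(.y ~ ., data = df_train,
                                     family = stats::binomial()))
  p_train <- suppressWarnings(stats::predict(fit, df_train, type = "response"))
  p_test <- suppressWarnings(stats::predict(fit, df_test, type = "response"))
  list(selected = selected, fallback = fallback,
       train = classifier_metrics(y_train, p_train),
       test = classifier_metrics(y_test, p_test))
}

#' Embedded feature-selection configuration
#'
#' Knobs for the nested-bootstrap embedded feature selection used by the
#' random-forest and SVM pipelines.
#'
#' @param n_trees trees per random forest.
#' @param n_importance inner-loop bootstrap refits over which variable
#'   importance is averaged.
#' @param n_val bootstrap train/out-of-bag splits used to estimate the
#'   validation error of each candidate subset.
#' @param max_subset longest ranking prefix examined by the forward
#'   search.
#' @param svm_cost_grid candidate SVM cost values (tuned first).
#' @param svm_rank_folds cross-validation folds for the single-feature SVM
#'   ranking criterion (use `Inf` for leave-one-out).
#' @export
fs_config <- function(n_trees = 500L, n_importance = 100L, n_val = 25L,
                      max_subset = 20L, svm_cost_grid = c(0.1, 1, 10),
                      svm_rank_folds = 5L) {
  as.list(environment())
}

strat_boot <- function(y) {
  idx <- unlist(lapply(levels(y), function(l) {
    r <- which(y == l)
    r[sample.int(length(r), length(r), replace = TRUE)]
  }))
  sort(idx)
}

## Forward selection over a ranking prefix: validation error of each
## prefix estimated on out-of-bootstrap samples; global minimum wins,
## ties toward the smaller subset.
forward_select <- function(x, y, ranking, fit_fun, predict_fun, config) {
  max_k <- min(config$max_subset, length(ranking))
  val_err <- numeric(max_k)
  for (k in seq_len(max_k)) {
    feats <- ranking[seq_len(k)]
    errs <- vapply(seq_len(config$n_val), function(r) {
      idx <- strat_boot(y)
      oob <- setdiff(seq_along(y), unique(idx))
      if (length(oob) < 2L || length(unique(y[oob])) < 2L) return(NA_real_)
      fit <- fit_fun(x[idx, feats, drop = FALSE], y[idx])
      prob <- predict_fun(fit, x[oob, feats, drop = FALSE])
      cc <- confusion_counts(y[oob],
                             factor(ifelse(prob >= 0.5, levels(y)[2],
                                           levels(y)[1]),
                                    levels = levels(y)),
                             positive = levels(y)[2])
      1 - balanced_accuracy(cc)
    }, numeric(1))
    val_err[k] <- mean(errs, na.rm = TRUE)
  }
  list(best_k = which.min(val_err), val_error = val_err)
}

#' Random-forest pipeline with embedded feature selection
#'
#' Inner loop: random forests on stratified bootstrap resamples, variable
#' importance averaged across refits. Outer loop: stepwise forward
#' selection over the importance ranking, keeping the prefix that
#' minimizes the out-of-bootstrap validation (balanced) error; the final
#' forest is refit on the chosen subset.
#'
#' @param x,y training features and binary outcome.
#' @param config a [fs_config()].
#' @param seed integer seed.
#' @return A list with `ranking`, `subset`, `val_error`, and the fitted
#'   `model`; `predict_prob(model, newx)` in the result gives event
#'   probabilities.
#' @export
embedded_fs_rf <- function(x, y, config = fs_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- as.matrix(x)
  y <- factor(y)
  if (ncol(x) < 1L) stop("need >= 1 feature", call. = FALSE)
  if (ncol(x) == 1L) {
    ranking <- colnames(x)
  } else {
    imp <- numeric(ncol(x))
    for (b in seq_len(config$n_importance)) {
      idx <- strat_boot(y)
      rf <- randomForest::randomForest(x[idx, , drop = FALSE], y[idx],
                                       ntree = config$n_trees,
                                       importance = TRUE)
      imp <- imp + randomForest::importance(rf, type = 1L)[, 1]
    }
    ranking <- colnames(x)[order(imp, decreasing = TRUE)]
  }

  fit_fun <- function(xx, yy)
    randomForest::randomForest(xx, yy, ntree = config$n_trees)
  predict_fun <- function(fit, xx)
    stats::predict(fit, xx, type = "prob")[, 2]

  fs <- if (length(ranking) == 1L) list(best_k = 1L, val_error = NA_real_)
  else forward_select(x, y, ranking, fit_fun, predict_fun, config)
  subset <- ranking[seq_len(fs$best_k)]
  model <- fit_fun(x[, subset, drop = FALSE], y)
  list(ranking = ranking, subset = subset, val_error = fs$val_error,
       model = model, predict_prob = predict_fun)
}

#' SVM pipeline with embedded feature selection
#'
#' The cost hyperparameter is tuned first on the full feature set;
#' features are then ranked by their single-feature cross-validated
#' accuracy (best first) and the forward search of [embedded_fs_rf()] is
#' run over the ranking with SVM fits (linear kernel).
#'
#' @inheritParams embedded_fs_rf
#' @export
embedded_fs_svm <- function(x, y, config = fs_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- as.matrix(x)
  y <- factor(y)

  cv_acc <- function(xx, cost, folds) {
    folds <- if (is.finite(folds)) min(folds, nrow(xx)) else nrow(xx)
    fit <- e1071::svm(xx, y, kernel = "linear", cost = cost, cross = folds)
    fit$tot.accuracy
  }
  cost <- if (length(config$svm_cost_grid) > 1L) {
    accs <- vapply(config$svm_cost_grid, function(cst)
      cv_acc(x, cst, config$svm_rank_folds), numeric(1))
    config$svm_cost_grid[which.max(accs)]
  } else config$svm_cost_grid

  ranking <- if (ncol(x) == 1L) colnames(x) else {
    crit <- vapply(seq_len(ncol(x)), function(j)
      cv_acc(x[, j, drop = FALSE], cost, config$svm_rank_folds), numeric(1))
    colnames(x)[order(crit, decreasing = TRUE)]
  }

  fit_fun <- function(xx, yy)
    e1071::svm(xx, yy, kernel = "linear", cost = cost, probability = TRUE)
  predict_fun <- function(fit, xx) {
    pr <- attr(stats::predict(fit, xx, probability = TRUE), "probabilities")
    pr[, levels(y)[2]]
  }

  fs <- if (length(ranking) == 1L) list(best_k = 1L, val_error = NA_real_)
  else forward_select(x, y, ranking, fit_fun, predict_fun, config)
  subset <- ranking[seq_len(fs$best_k)]
  model <- fit_fun(x[, subset, drop = FALSE], y)
  list(ranking = ranking, subset = subset, val_error = fs$val_error,
       model = model, predict_prob = predict_fun, cost = cost)
}

#' Benchmark configuration
#'
#' @param n_boot bootstrap resamples for the B harmonization variants.
#' @param prior empirical-Bayes prior passed to [harmonize()].
#' @param smote_k SMOTE neighbor count.
#' @param nfolds folds for the LASSO penalty choice.
#' @param fs a [fs_config()] for the embedded-selection pipelines.
#' @param strict_train_only fit the harmonization on the training batch
#'   only and re-apply it to the test batches, instead of the default
#'   whole-cohort fit (harmonization is unsupervised in the outcome, so
#'   the default matches the published workflow).
#' @export
benchmark_config <- function(n_boot = 200L, prior = "nonparametric",
                             smote_k = 5L, nfolds = 10L, fs = fs_config(),
                             strict_train_only = FALSE) {
  as.list(environment())
}

#' Run the harmonization-vs-ML benchmark grid
#'
#' For each data version (untransformed and the four harmonization
#' variants) and each pipeline (`"mr"`, `"rf"`, `"svm"`): harmonize the
#' whole cohort (unsupervised in the outcome), split train/test by batch
#' label (train = reference batch, test = the rest), balance the training
#' fold with SMOTE, fit, and score on the untouched test fold.
#'
#' @param values numeric samples-by-features matrix.
#' @param batch per-sample batch labels defining the split.
#' @param outcome binary outcome vector.
#' @param covariates optional covariates, appended to the predictor set.
#' @param reference training/reference batch label (default: largest).
#' @param variants data versions to run.
#' @param pipelines pipelines to run.
#' @param config a [benchmark_config()].
#' @param seed integer seed governing harmonization, SMOTE and the
#'   pipelines.
#' @return A long data frame (`variant`, `pipeline`, `split`, `metric`,
#'   `value`) of class `"benchmark_result"`, with per-cell details
#'   (selected features) in `attr(, "details")`.
#' @export
run_benchmark <- function(values, batch, outcome, covariates = NULL,
                          reference = NULL,
                          variants = c("untransformed", "combat", "b-combat",
                                       "m-combat", "bm-combat"),
                          pipelines = c("mr", "rf", "svm"),
                          config = benchmark_config(), seed = 1L) {
  values <- check_values(values)
  batch <- check_batch(batch, nrow(values), warn_small = FALSE)
  stopifnot(length(outcome) == nrow(values), all(outcome %in% c(0, 1)))
  pipelines <- match.arg(pipelines, several.ok = TRUE)
  if (is.null(reference)) {
    tab <- table(batch)
    reference <- names(tab)[which.max(tab)]
  }
  train <- batch == reference
  if (!any(train) || all(train))
    stop("reference batch must leave both a train and a test set", call. = FALSE)
  y <- factor(outcome, levels = c(0, 1))
  for (part in list(y[train], y[!train]))
    if (nlevels(droplevels(part)) < 2L)
      stop("train or test split has a single outcome class", call. = FALSE)

  rows <- list()
  details <- list()
  for (vi in seq_along(variants)) {
    variant <- variants[vi]
    data_v <- if (variant == "untransformed") values
    else if (isTRUE(config$strict_train_only)) {
      fit <- harmonize(values[train, , drop = FALSE], batch[train],
                       covariates = if (!is.null(covariates))
                         covariates[train, , drop = FALSE],
                       variant = variant, prior = config$prior,
                       reference = if (variant %in% c("m-combat", "bm-combat"))
                         reference,
                       n_boot = config$n_boot, seed = seed + vi)
      out <- values
      out[train, ] <- fitted(fit)
      ## test batches were unseen by a train-only fit; they stay raw and
      ## this mode documents exactly that limitation
      out
    } else {
      fitted(harmonize(values, batch, covariates = covariates,
                       variant = variant, prior = config$prior,
                       reference = if (variant %in% c("m-combat", "bm-combat"))
                         reference,
                       n_boot = config$n_boot, seed = seed + vi))
    }
    pred <- if (!is.null(covariates)) cbind(data_v, covariates) else data_v

    sm <- smote_oversample(pred[train, , drop = FALSE], y[train],
                           k_neighbors = config$smote_k,
                           seed = seed + 100L * vi)
    x_test <- pred[!train, , drop = FALSE]
    y_test <- y[!train]

    for (pl in pipelines) {
      pseed <- seed + 100L * vi + match(pl, c("mr", "rf", "svm"))
      res <- switch(pl,
        mr = mr_lasso_pipeline(sm$x, sm$y, x_test, y_test,
                               nfolds = config$nfolds, seed = pseed),
        rf = ,
        svm = {
          fs <- if (pl == "rf")
            embedded_fs_rf(sm$x, sm$y, config = config$fs, seed = pseed)
          else embedded_fs_svm(sm$x, sm$y, config = config$fs, seed = pseed)
          xs_train <- sm$x[, fs$subset, drop = FALSE]
          xs_test <- x_test[, fs$subset, drop = FALSE]
          list(selected = fs$subset,
               train = classifier_metrics(sm$y,
                                          fs$predict_prob(fs$model, xs_train)),
               test = classifier_metrics(y_test,
                                         fs$predict_prob(fs$model, xs_test)))
        })
      details[[paste(variant, pl, sep = ".")]] <- res$selected
      for (split in c("train", "test"))
        rows[[length(rows) + 1L]] <- data.frame(
          variant = variant, pipeline = pl, split = split,
          metric = names(res[[split]]), value = unname(res[[split]]),
          stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "details") <- details
  attr(out, "reference") <- reference
  class(out) <- c("benchmark_result", "data.frame")
  out
}
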