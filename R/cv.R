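#' Nested cross-validation configuration
#'
#' @param outer_folds,inner_folds Fold counts (default 5 and 5).
#' @param seed Integer seed controlling fold assignment and the
#'   stochastic parts of tree fitting.
#' @param variance_threshold Cumulative explained-variance fraction at
#'   which PCA is truncated (default 0.90).
#' @param grid Named list of hyperparameter value vectors:
#'   `max_tree_depth`, `min_child_weight`, `column_subsample_ratio`.
#' @param grouping `"none"` for plain stratified folds, or
#'   `"by_subject"` to keep all rows of a subject in the same fold
#'   (prevents leakage when lesion and reference rows of one patient are
#'   both present).
#' @param nrounds,eta Boosting rounds and learning rate of the
#'   gradient-boosted tree fits (defaults 50 and 0.3).
#' @param threshold Decision threshold on the predicted probability
#'   (default 0.5).
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 5, inner_folds = 5, seed = 1,
                      variance_threshold = 0.90,
                      grid = list(max_tree_depth = c(2, 3, 4, 6),
                                  min_child_weight = c(1, 3, 5),
                                  column_subsample_ratio = c(0.5, 0.75, 1.0)),
                      grouping = c("none", "by_subject"),
                      nrounds = 50, eta = 0.3, threshold = 0.5) {
  grouping <- match.arg(grouping)
  if (outer_folds < 2 || inner_folds < 2) {
    stop_dynomics("fold counts must be >= 2", class = "dynomics_cv_error")
  }
  if (variance_threshold <= 0 || variance_threshold > 1) {
    stop_dynomics("`variance_threshold` must be in (0, 1]",
                  class = "dynomics_cv_error")
  }
  need <- c("max_tree_depth", "min_child_weight", "column_subsample_ratio")
  if (!all(need %in% names(grid)) || any(lengths(grid[need]) == 0)) {
    stop_dynomics("`grid` must provide nonempty max_tree_depth, min_child_weight and column_subsample_ratio",
                  class = "dynomics_cv_error")
  }
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed),
                 variance_threshold = variance_threshold,
                 grid = grid[need], grouping = grouping,
                 nrounds = as.integer(nrounds), eta = eta,
                 threshold = threshold),
            class = "cv_config")
}

# stratified (optionally grouped) fold assignment; returns an integer
# vector of fold ids per row. Uses the current RNG state.
make_stratified_folds <- function(labels, k, groups = NULL) {
  n <- length(labels)
  fold <- integer(n)
  if (is.null(groups)) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        stop_dynomics(sprintf(
          "class '%s' has %d samples, fewer than %d folds", cl,
          length(idx), k), class = "dynomics_cv_error")
      }
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    gu <- unique(groups)
    # a group's stratum is its label when unique, else a joint stratum
    glab <- vapply(gu, function(g) {
      l <- unique(labels[groups == g])
      if (length(l) == 1) as.character(l) else "(mixed)"
    }, character(1))
    gfold <- integer(length(gu))
    for (cl in unique(glab)) {
      idx <- which(glab == cl)
      gfold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
    fold <- gfold[match(groups, gu)]
    # every fold's training part must still contain both classes
    for (f in seq_len(k)) {
      if (length(unique(labels[fold != f])) < length(unique(labels))) {
        stop_dynomics("grouped folds leave a class absent from training",
                      class = "dynomics_cv_error")
      }
    }
  }
  fold
}

#' Standardize feature columns on the training set and apply to the test set
#'
#' Centers and scales every column with training-set mean and standard
#' deviation (population convention, 1/N, matching the common
#' machine-learning scaler). Zero-variance training columns (e.g. shape
#' features after temporal MAD) cannot be scaled: they are mapped to 0 in
#' both sets and reported in the standardizer, so no NaN can propagate.
#'
#' @param train,test Numeric matrices with identical columns (`test` may
#'   be `NULL`).
#' @return List with `train`, `test` (transformed) and `standardizer`
#'   (`center`, `scale`, `zero_variance` column names).
#' @export
standardize_fit_apply <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2) {
    stop_dynomics("training matrix needs >= 2 rows",
                  class = "dynomics_cv_error")
  }
  center <- colMeans(train)
  scale_ <- sqrt(colMeans(sweep(train, 2, center, "-")^2))
  zero <- !is.finite(scale_) | scale_ < 1e-12
  scale_[zero] <- 1
  tr <- sweep(sweep(train, 2, center, "-"), 2, scale_, "/")
  tr[, zero] <- 0
  te <- NULL
  if (!is.null(test)) {
    test <- as.matrix(test)
    if (ncol(test) != ncol(train)) {
      stop_dynomics("train and test must share columns",
                    class = "dynomics_cv_error")
    }
    te <- sweep(sweep(test, 2, center, "-"), 2, scale_, "/")
    te[, zero] <- 0
  }
  list(train = tr, test = te,
       standardizer = list(center = center, scale = scale_,
                           zero_variance = colnames(train)[zero]))
}

#' PCA reduction truncated at a cumulative explained-variance threshold
#'
#' Fits principal components on the (already standardized) training
#' matrix only and projects both sets onto the smallest number of leading
#' components whose cumulative explained variance reaches the threshold.
#' Loadings follow the sign convention that each component's
#' largest-magnitude entry is positive, making reruns comparable.
#'
#' @param train,test Standardized numeric matrices (`test` may be
#'   `NULL`).
#' @param variance_threshold Fraction of total variance to retain
#'   (default 0.90; 1.0 keeps the full rank).
#' @return List with `train` and `test` score matrices (columns
#'   `PC1..PCk`), `loadings` (features x k), `eigenvalues` (all),
#'   `explained_variance` (fractions), and `k`.
#' @export
pca_reduce <- function(train, test = NULL, variance_threshold = 0.90) {
  train <- as.matrix(train)
  sv <- svd(train)
  eig <- sv$d^2 / max(nrow(train) - 1, 1)
  tot <- sum(eig)
  if (tot <= 1e-12) {
    stop_dynomics("degenerate all-zero matrix: no variance to reduce",
                  class = "dynomics_cv_error")
  }
  expl <- eig / tot
  nonzero <- sum(eig > 1e-12 * eig[1])
  k <- min(which(cumsum(expl) >= variance_threshold - 1e-12))
  k <- min(k, nonzero)
  rot <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| entry of each component positive
  for (c_ in seq_len(k)) {
    m <- which.max(abs(rot[, c_]))
    if (rot[m, c_] < 0) rot[, c_] <- -rot[, c_]
  }
  rownames(rot) <- colnames(train)
  colnames(rot) <- paste0("PC", seq_len(k))
  scores_tr <- train %*% rot
  scores_te <- if (!is.null(test)) as.matrix(test) %*% rot else NULL
  list(train = scores_tr, test = scores_te, loadings = rot,
       eigenvalues = eig, explained_variance = expl, k = k)
}

# deterministic xgboost fit
fit_gbt <- function(X, y, params, nrounds, eta, seed) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  eval_metric = "logloss",
                  # exact greedy splits: on cohort-sized data the
                  # histogram approximation puts cut points on training
                  # values at the edge of a class gap instead of its
                  # midpoint, which hurts generalization
                  tree_method = "exact",
                  max_depth = as.integer(params$max_tree_depth),
                  min_child_weight = params$min_child_weight,
                  colsample_bytree = params$column_subsample_ratio,
                  eta = eta, nthread = 1,
                  seed = as.integer(seed %% .Machine$integer.max)),
    data = dtrain, nrounds = nrounds, verbose = 0)
}

#' Inner-loop hyperparameter grid search
#'
#' Scores every grid point by mean inner-fold AUC. Within each inner
#' split, standardization and PCA are fit on the inner-training rows
#' only and applied to the held-out rows, mirroring the outer-loop
#' transform discipline. Ties break deterministically to the first grid
#' point in row order.
#'
#' @param X Numeric feature matrix of the outer-training rows (raw, not
#'   yet standardized).
#' @param y Binary 0/1 labels.
#' @param config A [cv_config()].
#' @return List with `best` (named list of the chosen values) and
#'   `scores` (tibble of the grid with mean inner AUC).
#' @export
inner_search <- function(X, y, config) {
  grid <- expand.grid(config$grid, KEEP.OUT.ATTRS = FALSE)
  if (length(unique(y)) < 2) {
    stop_dynomics("both classes must be present for the inner search",
                  class = "dynomics_cv_error")
  }
  fold <- make_stratified_folds(y, config$inner_folds)
  splits <- lapply(seq_len(config$inner_folds), function(f) {
    tr <- which(fold != f); te <- which(fold == f)
    st <- standardize_fit_apply(X[tr, , drop = FALSE],
                                X[te, , drop = FALSE])
    pc <- pca_reduce(st$train, st$test, config$variance_threshold)
    list(train = pc$train, test = pc$test, ytr = y[tr], yte = y[te])
  })
  auc_mean <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    aucs <- vapply(splits, function(s) {
      if (length(unique(s$yte)) < 2) return(NA_real_)
      bst <- fit_gbt(s$train, s$ytr, as.list(grid[g, ]), config$nrounds,
                     config$eta, config$seed + g)
      scores <- predict(bst, as.matrix(s$test))
      auc_mann_whitney(s$yte, scores)
    }, numeric(1))
    auc_mean[g] <- mean(aucs, na.rm = TRUE)
  }
  best <- which.max(auc_mean) # which.max takes the first maximum: grid order
  list(best = as.list(grid[best, ]),
       scores = dplyr::bind_cols(as_tibble(grid),
                                 tibble(mean_inner_auc = auc_mean)))
}

# AUC by the rank (Mann-Whitney) statistic with tie correction
auc_mann_whitney <- function(labels, scores) {
  y <- as.integer(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores) # average ranks handle ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from labels and predicted scores
#'
#' AUC is the rank (Mann-Whitney) statistic with tie correction;
#' accuracy, precision and recall use the decision threshold, with
#' precision and recall reported for each class in turn as positive.
#' With a single observed class, AUC is undefined and reported as `NA`.
#'
#' @param labels Factor or character labels (two classes).
#' @param scores Predicted probability of the positive class, in
#'   \[0, 1\].
#' @param threshold Decision threshold (default 0.5).
#' @param positive Label of the positive class; defaults to the last
#'   factor level.
#' @return A list of class `performance_report`: `auc`, `accuracy`,
#'   `per_class` (tibble of class, precision, recall), `n`, `positive`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5,
                            positive = NULL) {
  if (any(scores < -1e-9 | scores > 1 + 1e-9)) {
    stop_dynomics("scores must lie in [0, 1]", class = "dynomics_cv_error")
  }
  labels <- as.factor(labels)
  lev <- levels(droplevels(labels))
  positive <- positive %||% levels(labels)[nlevels(labels)]
  y <- as.integer(labels == positive)
  auc <- if (length(lev) < 2) NA_real_ else auc_mann_whitney(y, scores)
  pred_pos <- scores >= threshold
  negative <- setdiff(levels(labels), positive)[1] # NA if single-level
  pred <- ifelse(pred_pos, positive, negative)
  accuracy <- mean(!is.na(pred) & pred == as.character(labels))
  per_class <- dplyr::bind_rows(lapply(levels(labels), function(cl) {
    tp <- sum(pred %in% cl & labels == cl)
    fp <- sum(pred %in% cl & labels != cl)
    fn <- sum(!pred %in% cl & labels == cl)
    tibble(class = cl,
           precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
           recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  }))
  structure(list(auc = auc, accuracy = accuracy, per_class = per_class,
                 n = length(labels), positive = positive,
                 threshold = threshold),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> n = %d, AUC = %s, accuracy = %.3f\n",
              x$n, ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)),
              x$accuracy))
  print(x$per_class)
  invisible(x)
}

#' Nested stratified cross-validation of a design matrix
#'
#' Outer folds estimate performance; within each outer-training set an
#' inner grid search ([inner_search()]) selects hyperparameters, then
#' standardization and PCA (fit on the outer-training rows only) feed a
#' gradient-boosted tree classifier that scores the held-out rows.
#' Metrics are computed from the pooled out-of-fold predictions, so every
#' sample is scored exactly once.
#'
#' @param design A `design_matrix` from [assemble_design_matrix()], or
#'   any tibble with `sample_id`, `label` and numeric feature columns.
#' @param config A [cv_config()].
#' @param groups Optional grouping vector (one entry per row) used when
#'   `config$grouping == "by_subject"`; defaults to the part of
#'   `sample_id` before the last `"_"`.
#' @param positive Positive-class label (default: last factor level).
#' @return A list of class `dyno_cv`: `report` (a `performance_report`),
#'   `predictions` (pooled out-of-fold tibble), `folds` (per-fold
#'   models: standardizer, PCA, booster, chosen hyperparameters, test
#'   scores), `per_fold` metrics tibble, and the `config`.
#' @export
nested_cv <- function(design, config = cv_config(), groups = NULL,
                      positive = NULL) {
  feats <- design_feature_cols(design)
  X <- as.matrix(design[feats])
  storage.mode(X) <- "double"
  labels <- as.factor(design$label)
  if (nlevels(droplevels(labels)) != 2) {
    stop_dynomics("nested_cv requires exactly two classes",
                  class = "dynomics_cv_error")
  }
  positive <- positive %||% levels(labels)[nlevels(labels)]
  y <- as.integer(labels == positive)

  if (config$grouping == "by_subject" && is.null(groups)) {
    groups <- sub("_[^_]*$", "", design$sample_id)
  }
  if (config$grouping == "none") groups <- NULL

  set.seed(config$seed)
  fold <- make_stratified_folds(labels, config$outer_folds, groups)

  folds <- vector("list", config$outer_folds)
  preds <- vector("list", config$outer_folds)
  for (f in seq_len(config$outer_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    search <- inner_search(X[tr, , drop = FALSE], y[tr], config)
    st <- standardize_fit_apply(X[tr, , drop = FALSE], X[te, , drop = FALSE])
    pc <- pca_reduce(st$train, st$test, config$variance_threshold)
    bst <- fit_gbt(pc$train, y[tr], search$best, config$nrounds, config$eta,
                   config$seed + 1000 * f)
    scores <- predict(bst, pc$test)
    folds[[f]] <- list(
      fold = f, standardizer = st$standardizer,
      loadings = pc$loadings, eigenvalues = pc$eigenvalues,
      explained_variance = pc$explained_variance, k = pc$k,
      booster = bst, hyperparameters = search$best,
      inner_scores = search$scores,
      test_rows = te, test_scores = pc$test)
    preds[[f]] <- tibble(sample_id = design$sample_id[te],
                         label = as.character(labels[te]),
                         score = scores, fold = f)
  }
  predictions <- dplyr::bind_rows(preds)
  report <- compute_metrics(factor(predictions$label, levels(labels)),
                            predictions$score, config$threshold, positive)
  per_fold <- dplyr::bind_rows(lapply(folds, function(fm) {
    p <- preds[[fm$fold]]
    m <- compute_metrics(factor(p$label, levels(labels)), p$score,
                         config$threshold, positive)
    tibble(fold = fm$fold, n_test = nrow(p), auc = m$auc,
           accuracy = m$accuracy, k_components = fm$k,
           max_tree_depth = fm$hyperparameters$max_tree_depth,
           min_child_weight = fm$hyperparameters$min_child_weight,
           column_subsample_ratio = fm$hyperparameters$column_subsample_ratio)
  }))
  structure(list(report = report, predictions = predictions, folds = folds,
                 per_fold = per_fold, config = config, positive = positive,
                 feature_names = feats,
                 mode = attr(design, "mode") %||% "unknown"),
            class = "dyno_cv")
}

#' @export
print.dyno_cv <- function(x, ...) {
  cat(sprintf("<dyno_cv> %d outer folds, mode '%s'\n",
              x$config$outer_folds, x$mode))
  print(x$report)
  invisible(x)
}
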