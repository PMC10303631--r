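# random two-class design matrix fixture; `signal` shifts every column
# of class B, the way a global uptake difference moves all radiomic
# features at once (so the leading PCA components carry it)
random_design <- function(n = 40, m = 8, signal = 0, seed = 1,
                          labels = NULL) {
  set.seed(seed)
  lab <- labels %||% rep(c("A", "B"), length.out = n)
  X <- matrix(rnorm(n * m), n, m)
  X[lab == "B", ] <- X[lab == "B", ] + signal
  colnames(X) <- paste0("f", seq_len(m))
  d <- dplyr::bind_cols(tibble::tibble(sample_id = paste0("S", seq_len(n)),
                                       label = lab),
                        tibble::as_tibble(X))
  class(d) <- c("design_matrix", class(d))
  d
}

test_that("standardization is fit on train and applied to test", {
  st <- standardize_fit_apply(matrix(c(1, 3), 2, 1),
                              matrix(c(2, 4), 2, 1))
  expect_equal(as.vector(st$train), c(-1, 1)) # center 2, population sd 1
  expect_equal(st$standardizer$center, c(2), ignore_attr = TRUE)
  # test transformed with train statistics, not its own
  expect_equal(as.vector(st$test), c(0, 2))
  # zero-variance columns map to 0 in both sets without NaN
  tr <- matrix(c(1, 1, 1, 2, 5, 8), 3, 2,
               dimnames = list(NULL, c("flat", "x")))
  te <- matrix(c(9, 9, 1, 2), 2, 2, dimnames = list(NULL, c("flat", "x")))
  st2 <- standardize_fit_apply(tr, te)
  expect_equal(st2$train[, "flat"], c(0, 0, 0))
  expect_equal(st2$test[, "flat"], c(0, 0)) # even though test differs
  expect_equal(st2$standardizer$zero_variance, "flat")
  expect_false(anyNA(st2$train) || anyNA(st2$test))
  expect_error(standardize_fit_apply(matrix(1, 1, 1)),
               class = "dynomics_cv_error")
})

test_that("PCA truncation retains the smallest sufficient rank", {
  set.seed(3)
  # rank-1 latent factor plus tiny noise: one component suffices
  z <- rnorm(30)
  X1 <- outer(z, rep(1, 6)) + matrix(rnorm(180, sd = 1e-4), 30, 6)
  st <- standardize_fit_apply(X1)
  pc1 <- pca_reduce(st$train, variance_threshold = 0.9)
  expect_equal(pc1$k, 1)
  # isotropic data: k checked against the eigen-decomposition oracle
  X2 <- matrix(rnorm(600), 60, 10)
  colnames(X2) <- paste0("f", 1:10)
  st2 <- standardize_fit_apply(X2)
  pc2 <- pca_reduce(st2$train, variance_threshold = 0.9)
  ev <- sort(eigen(stats::cov(st2$train))$values, decreasing = TRUE)
  k_want <- min(which(cumsum(ev) / sum(ev) >= 0.9))
  expect_equal(pc2$k, k_want)
  expect_equal(pc2$eigenvalues, ev, tolerance = 1e-8)
  # threshold 1.0 keeps the full rank
  pc_full <- pca_reduce(st2$train, variance_threshold = 1.0)
  expect_equal(pc_full$k, 10)
  # test rows are projected with train loadings
  pc3 <- pca_reduce(st2$train[1:50, ], st2$train[51:60, ], 0.9)
  expect_equal(pc3$test,
               st2$train[51:60, ] %*% pc3$loadings)
  # largest-|loading| entry of every component is positive
  for (c_ in seq_len(pc2$k)) {
    expect_gt(pc2$loadings[which.max(abs(pc2$loadings[, c_])), c_], 0)
  }
  expect_error(pca_reduce(matrix(0, 5, 3)), class = "dynomics_cv_error")
})

test_that("metrics match rank-statistic and confusion-table oracles", {
  m <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1), positive = "1")
  expect_equal(m$auc, 0.75) # 3 of 4 label pairs correctly ordered
  expect_equal(m$accuracy, 0.5)
  m2 <- compute_metrics(c("a", "a", "b", "b"), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(m2$auc, 1)
  expect_equal(m2$accuracy, 1)
  expect_equal(m2$per_class$precision, c(1, 1))
  expect_equal(m2$per_class$recall, c(1, 1))
  # all-tied scores: AUC 0.5 under the tie correction
  m3 <- compute_metrics(c(1, 0, 1, 0), rep(0.5, 4), positive = "1")
  expect_equal(m3$auc, 0.5)
  # single observed class: AUC undefined
  m4 <- compute_metrics(c("a", "a"), c(0.1, 0.9), positive = "a")
  expect_true(is.na(m4$auc))
  # agreement with an independent ROC implementation on random data
  skip_if_not_installed("pROC")
  set.seed(10)
  for (i in 1:5) {
    y <- sample(c(0, 1), 50, replace = TRUE)
    s <- round(runif(50), 2) # rounding forces ties
    want <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                           direction = "<")))
    got <- compute_metrics(y, s, positive = "1")$auc
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("the inner grid search is deterministic and finds separability", {
  d <- random_design(n = 40, m = 5, signal = 3, seed = 2)
  X <- as.matrix(d[paste0("f", 1:5)])
  y <- as.integer(d$label == "B")
  cfg1 <- cv_config(seed = 5, grid = list(max_tree_depth = 2,
                                          min_child_weight = 1,
                                          column_subsample_ratio = 1))
  set.seed(cfg1$seed)
  s1 <- inner_search(X, y, cfg1)
  expect_equal(s1$best$max_tree_depth, 2) # single-point grid returns it
  expect_gte(max(s1$scores$mean_inner_auc), 0.95) # separable construction
  cfg2 <- cv_config(seed = 5, grid = list(max_tree_depth = c(2, 3),
                                          min_child_weight = c(1, 3),
                                          column_subsample_ratio = c(0.5, 1)))
  set.seed(cfg2$seed); s2a <- inner_search(X, y, cfg2)
  set.seed(cfg2$seed); s2b <- inner_search(X, y, cfg2)
  expect_identical(s2a$best, s2b$best) # fixed seed, identical selection
  expect_identical(s2a$scores, s2b$scores)
})

test_that("stratified folds partition samples and respect groups", {
  lab <- rep(c("A", "B"), c(12, 18))
  set.seed(1)
  f <- make_stratified_folds(lab, 5)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f, lab) >= 2)) # stratification balance
  # grouped: both rows of a subject land in the same fold
  subj <- rep(paste0("P", 1:15), each = 2)
  lab2 <- rep(c("lesion", "reference"), 15)
  f2 <- make_stratified_folds(lab2, 5, groups = subj)
  for (p in unique(subj)) {
    expect_equal(length(unique(f2[subj == p])), 1)
  }
  expect_error(make_stratified_folds(rep(c("A", "B"), c(3, 30)), 5),
               class = "dynomics_cv_error")
})

small_grid <- list(max_tree_depth = c(2, 3), min_child_weight = 1,
                   column_subsample_ratio = c(0.75, 1))

test_that("nested CV scores every sample exactly once and is seeded", {
  d <- random_design(n = 40, m = 6, signal = 8, seed = 4)
  cfg <- cv_config(seed = 11, grid = small_grid)
  cv <- nested_cv(d, cfg)
  expect_setequal(cv$predictions$sample_id, d$sample_id)
  expect_equal(nrow(cv$predictions), nrow(d)) # partition property
  # separable two-class design: perfect pooled metrics
  expect_equal(cv$report$accuracy, 1.0)
  expect_equal(cv$report$auc, 1.0)
  # retained components satisfy the variance threshold on every fold
  for (fm in cv$folds) {
    expect_gte(sum(fm$explained_variance[seq_len(fm$k)]), 0.90 - 1e-9)
  }
  # end-to-end determinism
  cv2 <- nested_cv(d, cfg)
  expect_equal(cv$predictions, cv2$predictions)
  expect_equal(glance(cv), glance(cv2))
  # broom-style accessors
  expect_equal(nrow(tidy(cv)), 5)
  expect_equal(nrow(glance(cv)), 1)
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("train-derived transforms ignore test rows (no leakage)", {
  d <- random_design(n = 30, m = 5, signal = 2, seed = 6)
  cfg <- cv_config(seed = 2, grid = small_grid)
  cv <- nested_cv(d, cfg)
  fm <- cv$folds[[1]]
  X <- as.matrix(d[paste0("f", 1:5)])
  train_rows <- setdiff(seq_len(nrow(d)), fm$test_rows)
  # recompute the standardizer and PCA from training rows alone, with one
  # test row deleted: identical transforms
  st <- standardize_fit_apply(X[train_rows, ],
                              X[fm$test_rows[-1], , drop = FALSE])
  expect_equal(st$standardizer$center, fm$standardizer$center)
  expect_equal(st$standardizer$scale, fm$standardizer$scale)
  pc <- pca_reduce(st$train, st$test, cfg$variance_threshold)
  expect_equal(pc$loadings, fm$loadings)
  expect_equal(pc$test, fm$test_scores[-1, , drop = FALSE])
})

test_that("label permutation yields chance-level AUC", {
  set.seed(77)
  d <- random_design(n = 200, m = 10, signal = 0, seed = 77,
                     labels = sample(rep(c("A", "B"), 100)))
  cfg <- cv_config(seed = 77, grid = list(max_tree_depth = 2,
                                          min_child_weight = 3,
                                          column_subsample_ratio = 1))
  cv <- nested_cv(d, cfg)
  expect_gte(cv$report$auc, 0.3)
  expect_lte(cv$report$auc, 0.7)
})
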