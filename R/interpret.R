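#' Shapley-value attribution of principal components
#'
#' Computes exact tree-path Shapley values of every retained principal
#' component for each out-of-fold sample of a fitted [nested_cv()]
#' result, and aggregates them as the mean absolute value per component
#' across all pooled test rows and folds (components a fold did not
#' retain contribute zero for that fold's rows). The decomposition is
#' additive: per sample, the component values plus the base value equal
#' the model's margin prediction.
#'
#' @param cv A `dyno_cv` object from [nested_cv()].
#' @return A list of class `attribution_report`: `components` (tibble of
#'   component, mean_abs_shap, rank, sorted descending), and `per_sample`
#'   (long tibble of per-sample Shapley values with fold and base
#'   value).
#' @export
shapley_attribution <- function(cv) {
  if (!inherits(cv, "dyno_cv")) {
    stop_dynomics("`cv` must be a dyno_cv object",
                  class = "dynomics_type_error")
  }
  rows <- list()
  total_abs <- numeric(0)
  n_rows <- 0
  for (fm in cv$folds) {
    contrib <- predict(fm$booster, as.matrix(fm$test_scores),
                       predcontrib = TRUE)
    if (ncol(contrib) != fm$k + 1) {
      stop_dynomics("model/feature-dimension mismatch in attribution",
                    class = "dynomics_type_error")
    }
    colnames(contrib) <- c(colnames(fm$test_scores), "BIAS")
    comp_cols <- setdiff(colnames(contrib), "BIAS")
    n_rows <- n_rows + nrow(contrib)
    for (cc in comp_cols) {
      total_abs[cc] <- (if (cc %in% names(total_abs)) total_abs[cc] else 0) +
        sum(abs(contrib[, cc]))
    }
    rows[[length(rows) + 1]] <- as_tibble(contrib) |>
      dplyr::mutate(fold = fm$fold, row = fm$test_rows) |>
      tidyr::pivot_longer(dplyr::all_of(comp_cols),
                          names_to = "component", values_to = "shap") |>
      dplyr::rename(base_value = "BIAS")
  }
  comp <- tibble(component = names(total_abs),
                 mean_abs_shap = as.numeric(total_abs) / n_rows) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_shap)) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(list(components = comp, per_sample = dplyr::bind_rows(rows)),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat("<attribution_report> component ranking by mean |Shapley value|\n")
  print(x$components)
  invisible(x)
}

#' Highest-loading original features of a principal component
#'
#' Orders the original features by the magnitude of their loading
#' (eigenvector entry) on one component and returns the top `k` with
#' their signed loadings.
#'
#' @param loadings Numeric loading matrix (features x components) with
#'   feature row names, e.g. from [pca_reduce()].
#' @param component Component index or `"PC<j>"` name.
#' @param k Number of features to return (default 5).
#' @return A tibble with `feature`, `loading` and `rank`.
#' @export
top_loadings <- function(loadings, component, k = 5) {
  if (is.character(component)) {
    component <- match(component, colnames(loadings))
  }
  if (is.na(component) || component < 1 || component > ncol(loadings)) {
    stop_dynomics("invalid component index", class = "dynomics_type_error")
  }
  if (k > nrow(loadings)) {
    stop_dynomics("`k` exceeds the number of features",
                  class = "dynomics_type_error")
  }
  v <- loadings[, component]
  ord <- order(abs(v), decreasing = TRUE)[seq_len(k)]
  tibble(feature = rownames(loadings)[ord], loading = unname(v[ord]),
         rank = seq_len(k))
}

#' Component attribution with top-loading feature table
#'
#' Combines the Shapley component ranking of a fitted cross-validation
#' with a whole-dataset standardize-then-PCA loading table (computed once
#' and used for interpretation only, never for performance claims): the
#' top-ranked component is mapped back to its `k` highest-loading
#' original features and its explained variance.
#'
#' @param cv A `dyno_cv` object.
#' @param design The `design_matrix` the model was fitted on.
#' @param k Number of top features to report (default 5).
#' @return A list of class `attribution_report` extended with
#'   `top_component`, `top_features` (tibble), `explained_variance` of
#'   the top component and the full whole-dataset `loadings`.
#' @export
explain_components <- function(cv, design, k = 5) {
  att <- shapley_attribution(cv)
  feats <- design_feature_cols(design)
  X <- as.matrix(design[feats])
  storage.mode(X) <- "double"
  st <- standardize_fit_apply(X)
  pc <- pca_reduce(st$train,
                   variance_threshold = cv$config$variance_threshold)
  top <- att$components$component[1]
  top_idx <- as.integer(sub("^PC", "", top))
  if (top_idx > pc$k) top_idx <- pc$k # whole-data PCA may retain fewer
  out <- att
  out$top_component <- paste0("PC", top_idx)
  out$top_features <- top_loadings(pc$loadings, top_idx, k)
  out$explained_variance <- pc$explained_variance[top_idx]
  out$loadings <- pc$loadings
  out
}

#' Write an attribution report to JSON + CSV
#'
#' @param report An `attribution_report` from [explain_components()].
#' @param json_path Output JSON path (component ranking, top component,
#'   explained variance).
#' @param csv_path Optional output CSV path for the top-loading table.
#' @return `json_path` invisibly.
#' @export
write_attribution <- function(report, json_path, csv_path = NULL) {
  payload <- list(components = report$components,
                  top_component = report$top_component,
                  explained_variance = report$explained_variance)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path) && !is.null(report$top_features)) {
    readr::write_csv(report$top_features, csv_path)
  }
  invisible(json_path)
}
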