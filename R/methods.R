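#' Tidy per-fold results of a nested cross-validation
#'
#' @param x A `dyno_cv` object.
#' @param ... Unused.
#' @return A tibble with one row per outer fold: AUC, accuracy, retained
#'   component count and the chosen hyperparameters.
#' @method tidy dyno_cv
#' @export
tidy.dyno_cv <- function(x, ...) {
  x$per_fold
}

#' One-row summary of a nested cross-validation
#'
#' @param x A `dyno_cv` object.
#' @param ... Unused.
#' @return A 1-row tibble with pooled out-of-fold AUC, accuracy, per-class
#'   precision/recall, sample count and fold count.
#' @method glance dyno_cv
#' @export
glance.dyno_cv <- function(x, ...) {
  pc <- x$report$per_class
  wide <- stats::setNames(
    c(pc$precision, pc$recall),
    c(paste0("precision_", pc$class), paste0("recall_", pc$class)))
  dplyr::bind_cols(
    tibble(auc = x$report$auc, accuracy = x$report$accuracy),
    as_tibble(as.list(wide)),
    tibble(n = x$report$n, outer_folds = x$config$outer_folds,
           mode = x$mode))
}

#' ROC curve of pooled out-of-fold predictions
#'
#' @param object A `dyno_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dyno_cv
#' @export
autoplot.dyno_cv <- function(object, ...) {
  p <- object$predictions
  y <- as.integer(p$label == object$positive)
  ord <- order(p$score, decreasing = TRUE)
  tpr <- c(0, cumsum(y[ord]) / max(sum(y), 1))
  fpr <- c(0, cumsum(1 - y[ord]) / max(sum(1 - y), 1))
  df <- tibble(fpr = fpr, tpr = tpr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Pooled out-of-fold ROC (AUC = %.3f)",
                      object$report$auc)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Feature time-course plot
#'
#' Plots selected feature trajectories of a feature time series against
#' frame start time.
#'
#' @param object A `feature_timeseries` from [extract_per_frame()].
#' @param features Character vector of feature names to show (default:
#'   first-order Mean).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot feature_timeseries
#' @export
autoplot.feature_timeseries <- function(object,
                                        features = "firstorder/Mean", ...) {
  missing <- setdiff(features, names(object))
  if (length(missing) > 0) {
    stop_dynomics(paste0("unknown features: ", paste(missing, collapse = ", ")),
                  class = "dynomics_type_error")
  }
  df <- object |>
    dplyr::select(dplyr::all_of(c("start_s", features))) |>
    tidyr::pivot_longer(-"start_s", names_to = "feature")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "Frame start (s)", y = "Feature value") +
    ggplot2::theme_minimal()
}

#' Component-importance bar plot of a Shapley attribution
#'
#' @param object An `attribution_report` from [shapley_attribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot attribution_report
#' @export
autoplot.attribution_report <- function(object, ...) {
  df <- object$components
  df$component <- factor(df$component, levels = rev(df$component))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_abs_shap,
                                   y = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Mean |Shapley value|", y = NULL,
                  title = "Principal-component attribution") +
    ggplot2::theme_minimal()
}
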