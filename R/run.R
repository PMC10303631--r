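#' Resolve a run configuration
#'
#' Run configurations drive the four pipeline commands. A configuration
#' is a named list (or a YAML file containing one) with, depending on
#' the command: `out_dir`, `cohort_dir`, `features_dir`, `task`
#' (`tumor-vs-reference` or `cr-vs-pr`), `mode` (`static`, `median`,
#' `mad`, `median+mad`), `seed`, `n_cr`, `n_pr`, and optional nested
#' `cv` (passed to [cv_config()]) and `discretization` (passed to
#' [discretization_scheme()]) blocks.
#'
#' @param config A named list or path to a YAML file.
#' @return The resolved configuration list.
#' @export
resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop_dynomics(paste0("config file not found: ", config),
                    class = "dynomics_io_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stop_dynomics("`config` must be a list or YAML path",
                  class = "dynomics_io_error")
  }
  config
}

config_scheme <- function(config) {
  if (is.null(config$discretization)) return(discretization_scheme())
  do.call(discretization_scheme, config$discretization)
}

config_cv <- function(config, seed) {
  args <- config$cv %||% list()
  if (!is.null(seed)) args$seed <- seed
  do.call(cv_config, args)
}

#' Simulate a phantom cohort to disk
#'
#' Wraps [generate_cohort()]: builds the phantom configuration from the
#' run configuration (`n_cr`, `n_pr`, `seed`, optional `phantom` block
#' with [phantom_config()] fields) and writes NIfTI volumes, masks,
#' schedule and subject CSVs plus a JSON manifest of the resolved
#' configuration.
#'
#' @param config Run configuration (list or YAML path) with `out_dir`.
#' @param seed Optional seed override.
#' @return The manifest tibble, invisibly.
#' @export
run_simulate <- function(config, seed = NULL) {
  config <- resolve_config(config)
  if (is.null(config$out_dir)) {
    stop_dynomics("`out_dir` is required", class = "dynomics_io_error")
  }
  args <- config$phantom %||% list()
  if (!is.null(config$n_cr)) args$n_cr <- config$n_cr
  if (!is.null(config$n_pr)) args$n_pr <- config$n_pr
  args$seed <- seed %||% config$seed %||% 1
  pc <- do.call(phantom_config, args)
  manifest <- generate_cohort(pc, dir = config$out_dir)
  jsonlite::write_json(
    list(command = "simulate", seed = args$seed, n_cr = pc$n_cr,
         n_pr = pc$n_pr, grid = pc$grid, spacing = pc$spacing),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(manifest)
}

#' Extract features for a simulated or on-disk cohort
#'
#' Reads every subject listed in `<cohort_dir>/subjects.csv`, normalizes
#' to SUV, and writes per-VOI static features, per-frame feature time
#' series, and temporal median/MAD summaries as CSV tables under
#' `out_dir`.
#'
#' @param config Run configuration with `cohort_dir` and `out_dir`.
#' @return Invisibly, the list of written paths.
#' @export
run_extract <- function(config) {
  config <- resolve_config(config)
  cohort_dir <- config$cohort_dir
  out_dir <- config$out_dir %||% cohort_dir
  subjects <- readr::read_csv(file.path(cohort_dir, "subjects.csv"),
                              show_col_types = FALSE)
  scheme <- config_scheme(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stat_rows <- list(); dyn_rows <- list()
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    series <- read_dynamic_series(s$series_path,
                                  file.path(cohort_dir, "schedule.csv"))
    suv <- suv_normalize(series, s$dose_MBq, s$weight_kg)
    static <- make_static_image(suv)
    for (v in c("lesion", "reference")) {
      mask <- read_mask(s[[paste0(v, "_path")]])
      meta <- tibble(subject_id = s$subject_id, voi = v, class = s$label)
      stat_rows[[length(stat_rows) + 1]] <- dplyr::bind_cols(
        meta, extract_features(static, mask, scheme))
      fts <- extract_per_frame(suv, mask, scheme)
      dyn_rows[[length(dyn_rows) + 1]] <- dplyr::bind_cols(
        meta[rep(1, nrow(fts)), ], fts)
    }
  }
  static_tbl <- dplyr::bind_rows(stat_rows)
  dynamic_tbl <- dplyr::bind_rows(dyn_rows)
  paths <- list(static = file.path(out_dir, "features_static.csv"),
                timeseries = file.path(out_dir, "features_timeseries.csv"))
  readr::write_csv(static_tbl, paths$static)
  readr::write_csv(dynamic_tbl, paths$timeseries)
  jsonlite::write_json(list(discretization = unclass(scheme)),
                       file.path(out_dir, "extraction_settings.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Classify a cohort from extracted feature tables
#'
#' Assembles the design matrix for the requested task and mode from the
#' tables written by [run_extract()], runs [nested_cv()], and writes the
#' performance report JSON and the pooled out-of-fold predictions CSV.
#'
#' @param config Run configuration with `features_dir`, `task`, `mode`
#'   and `out_dir`.
#' @param seed Optional seed override.
#' @return The `dyno_cv` object, invisibly.
#' @export
run_classify <- function(config, seed = NULL) {
  config <- resolve_config(config)
  fd <- config$features_dir
  out_dir <- config$out_dir %||% fd
  task <- config$task %||% "tumor-vs-reference"
  mode <- config$mode %||% "static"
  feats <- list(
    static = readr::read_csv(file.path(fd, "features_static.csv"),
                             show_col_types = FALSE),
    dynamic = if (mode != "static")
      readr::read_csv(file.path(fd, "features_timeseries.csv"),
                      show_col_types = FALSE) else NULL)
  design <- design_from_features(feats, task, mode)
  cvc <- config_cv(config, seed %||% config$seed)
  if (task == "tumor-vs-reference" && is.null((config$cv %||% list())$grouping)) {
    cvc$grouping <- "by_subject" # both rows of a patient share a fold
  }
  cv <- nested_cv(design, cvc)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- paste0("classify_", task, "_", gsub("\\+", "-", mode))
  jsonlite::write_json(
    list(task = task, mode = mode, seed = cvc$seed,
         metrics = glance(cv), per_fold = tidy(cv)),
    file.path(out_dir, paste0(stem, ".json")), auto_unbox = TRUE,
    digits = NA)
  readr::write_csv(cv$predictions,
                   file.path(out_dir, paste0(stem, "_predictions.csv")))
  invisible(cv)
}

#' Explain a fitted classification via Shapley attribution
#'
#' Runs the classification for the configured task/mode (reusing
#' [run_classify()] machinery in memory), computes the Shapley component
#' attribution and the top-loading feature table, and writes them as
#' JSON + CSV.
#'
#' @param config Run configuration with `features_dir`, `task`, `mode`,
#'   `out_dir` and optional `top_k` (default 5).
#' @param seed Optional seed override.
#' @return The `attribution_report`, invisibly.
#' @export
run_explain <- function(config, seed = NULL) {
  config <- resolve_config(config)
  cv <- run_classify(config, seed)
  fd <- config$features_dir
  task <- config$task %||% "tumor-vs-reference"
  mode <- config$mode %||% "static"
  feats <- list(
    static = readr::read_csv(file.path(fd, "features_static.csv"),
                             show_col_types = FALSE),
    dynamic = if (mode != "static")
      readr::read_csv(file.path(fd, "features_timeseries.csv"),
                      show_col_types = FALSE) else NULL)
  design <- design_from_features(feats, task, mode)
  report <- explain_components(cv, design, k = config$top_k %||% 5)
  out_dir <- config$out_dir %||% fd
  stem <- paste0("explain_", task, "_", gsub("\\+", "-", mode))
  write_attribution(report, file.path(out_dir, paste0(stem, ".json")),
                    file.path(out_dir, paste0(stem, "_loadings.csv")))
  invisible(report)
}
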