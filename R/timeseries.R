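#' Per-frame feature extraction over a dynamic series
#'
#' Extracts the 107-feature vector independently for every frame of a
#' dynamic series within a fixed VOI. Each frame is discretized on its
#' own (under `fixed_bin_count`, each frame's own in-mask min/max span
#' the bins; set `global_discretization = TRUE` to discretize all frames
#' on the pooled range instead). The mask does not change over time, so
#' the shape family is computed once and replicated across rows.
#'
#' @param series A [dynamic_series()].
#' @param mask A [voi_mask()] on the same grid.
#' @param scheme A [discretization_scheme()].
#' @param glcm_distance,gldm_alpha Texture settings, see
#'   [extract_features()].
#' @param global_discretization If `TRUE`, a `fixed_bin_width` scheme
#'   spanning the pooled in-mask range of all frames replaces per-frame
#'   scaling.
#' @return A tibble of class `feature_timeseries` with columns `frame`,
#'   `start_s`, `duration_s` and the 107 canonical features; one row per
#'   frame.
#' @export
extract_per_frame <- function(series, mask, scheme = discretization_scheme(),
                              glcm_distance = 1, gldm_alpha = 0,
                              global_discretization = FALSE) {
  if (!inherits(series, "dynamic_series")) {
    stop_dynomics("`series` must be a dynamic_series",
                  class = "dynomics_type_error")
  }
  if (!identical(dim(series$data)[1:3], dim(mask$data))) {
    stop_dynomics("series and mask are on different grids",
                  class = "dynomics_grid_mismatch")
  }
  nf <- n_frames(series)
  if (global_discretization && scheme$mode == "fixed_bin_count") {
    pooled <- range(series$data[rep(mask$data, nf)])
    width <- diff(pooled) / scheme$n_bins
    if (width > 0) {
      scheme <- discretization_scheme("fixed_bin_width", bin_width = width)
    }
  }
  # crop once to the mask bounding box: every per-frame quantity depends
  # only on in-mask voxels, and frames of the full grid are large
  bb <- which(mask$data, arr.ind = TRUE)
  rx <- range(bb[, 1]); ry <- range(bb[, 2]); rz <- range(bb[, 3])
  sub <- series$data[rx[1]:rx[2], ry[1]:ry[2], rz[1]:rz[2], , drop = FALSE]
  mask_c <- voi_mask(crop_to_bbox(mask$data, mask$data), mask$spacing)
  shape_row <- shape3d_features(mask_c)
  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    rows[[f]] <- tryCatch(
      extract_features(volume3d(sub[, , , f, drop = TRUE], series$spacing),
                       mask_c, scheme,
                       glcm_distance = glcm_distance,
                       gldm_alpha = gldm_alpha, shape = shape_row),
      error = function(e) {
        stop_dynomics(sprintf("frame %d: %s", f, conditionMessage(e)),
                      class = "dynomics_feature_error")
      })
  }
  out <- dplyr::bind_cols(
    tibble(frame = seq_len(nf), start_s = series$schedule$start_s,
           duration_s = series$schedule$duration_s),
    dplyr::bind_rows(rows))
  class(out) <- c("feature_timeseries", class(out))
  attr(out, "schedule") <- series$schedule
  out
}

ts_meta_cols <- c("frame", "start_s", "duration_s")

ts_feature_cols <- function(fts) {
  setdiff(names(fts), c(ts_meta_cols, "sample_id", "subject_id", "voi",
                        "label", "class"))
}

#' Temporal median of a feature time series
#'
#' Per-feature median across frames (even frame counts average the two
#' middle order statistics).
#'
#' @param fts A `feature_timeseries` tibble from [extract_per_frame()].
#' @return A 1-row tibble with one column per feature.
#' @export
temporal_median <- function(fts) {
  cols <- ts_feature_cols(fts)
  if (nrow(fts) < 1) {
    stop_dynomics("at least one frame required", class = "dynomics_type_error")
  }
  as_tibble(lapply(fts[cols], median))
}

#' Temporal median absolute deviation of a feature time series
#'
#' Per-feature `median(|x_f - median(x)|)` across frames, unscaled (no
#' Gaussian consistency factor). Features that are constant over time
#' (e.g. every shape feature, since the mask is fixed) have MAD exactly
#' 0.
#'
#' @param fts A `feature_timeseries` tibble from [extract_per_frame()].
#' @return A 1-row tibble with one column per feature.
#' @export
temporal_mad <- function(fts) {
  cols <- ts_feature_cols(fts)
  if (nrow(fts) < 1) {
    stop_dynomics("at least one frame required", class = "dynomics_type_error")
  }
  as_tibble(lapply(fts[cols], function(x) median(abs(x - median(x)))))
}

#' Assemble a samples-by-features design matrix
#'
#' Builds the classifier input from per-sample features. For
#' `mode = "static"`, `x` must hold one row per sample with feature
#' columns. For the dynamic modes, `x` is a long table of per-frame
#' features (one row per sample and frame, as stacked
#' [extract_per_frame()] outputs) which is summarized per sample:
#' `median`, `mad`, or their concatenation `median+mad` whose columns are
#' suffixed `/median` and `/mad` (n x 2m).
#'
#' @param x A tibble with `sample_id`, `label`, feature columns, and for
#'   dynamic modes a `frame` column.
#' @param mode One of `"static"`, `"median"`, `"mad"`, `"median+mad"`.
#' @return A tibble of class `design_matrix` with `sample_id`, `label`
#'   and feature columns; the mode is stored in attribute `mode`.
#' @export
assemble_design_matrix <- function(x, mode = c("static", "median", "mad",
                                               "median+mad")) {
  mode <- match.arg(mode)
  if (!all(c("sample_id", "label") %in% names(x))) {
    stop_dynomics("`x` must have sample_id and label columns",
                  class = "dynomics_design_error")
  }
  if (anyNA(x$label)) {
    stop_dynomics("missing labels", class = "dynomics_design_error")
  }
  feats <- ts_feature_cols(x)
  if (length(feats) == 0) {
    stop_dynomics("no feature columns found", class = "dynomics_design_error")
  }
  if (mode == "static") {
    if (anyDuplicated(x$sample_id)) {
      stop_dynomics("static mode expects one row per sample",
                    class = "dynomics_design_error")
    }
    out <- x[c("sample_id", "label", feats)]
  } else {
    if (!"frame" %in% names(x)) {
      stop_dynomics("dynamic modes expect a `frame` column",
                    class = "dynomics_design_error")
    }
    summarize_one <- function(df, fun, suffix = NULL) {
      res <- df |>
        dplyr::group_by(.data$sample_id, .data$label) |>
        dplyr::summarize(dplyr::across(dplyr::all_of(feats), fun),
                         .groups = "drop")
      if (!is.null(suffix)) {
        names(res)[match(feats, names(res))] <- paste0(feats, "/", suffix)
      }
      res
    }
    tmed <- function(v) median(v)
    tmad <- function(v) median(abs(v - median(v)))
    out <- switch(mode,
      "median" = summarize_one(x, tmed),
      "mad" = summarize_one(x, tmad),
      "median+mad" = dplyr::inner_join(
        summarize_one(x, tmed, "median"),
        summarize_one(x, tmad, "mad"),
        by = c("sample_id", "label")))
  }
  if (anyNA(out)) {
    stop_dynomics("design matrix contains missing values",
                  class = "dynomics_design_error")
  }
  out <- as_tibble(out)
  class(out) <- c("design_matrix", class(out))
  attr(out, "mode") <- mode
  out
}

#' Feature columns of a design matrix
#' @param design A `design_matrix`.
#' @return Character vector of feature column names.
#' @export
design_feature_cols <- function(design) {
  setdiff(names(design), c("sample_id", "label"))
}

#' Export per-feature time courses as a labeled (n x m) x t table
#'
#' Reshapes stacked per-frame features into one row per (sample,
#' feature) with one column per frame, each row carrying the sample's
#' label — the input format for external sequence models.
#'
#' @param x Long tibble of per-frame features with `sample_id`, `label`,
#'   `frame` and feature columns.
#' @return A tibble with columns `sample_id`, `feature`, `label` and one
#'   `t<frame>` column per frame.
#' @export
export_timeseries_tensor <- function(x) {
  if (!all(c("sample_id", "label", "frame") %in% names(x))) {
    stop_dynomics("`x` must have sample_id, label and frame columns",
                  class = "dynomics_design_error")
  }
  counts <- table(x$sample_id)
  if (length(unique(counts)) != 1) {
    stop_dynomics("heterogeneous frame counts across samples",
                  class = "dynomics_design_error")
  }
  feats <- ts_feature_cols(x)
  x |>
    dplyr::select(dplyr::all_of(c("sample_id", "label", "frame", feats))) |>
    tidyr::pivot_longer(dplyr::all_of(feats), names_to = "feature") |>
    dplyr::mutate(frame = paste0("t", .data$frame)) |>
    tidyr::pivot_wider(names_from = "frame", values_from = "value") |>
    dplyr::arrange(.data$sample_id, .data$feature)
}
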