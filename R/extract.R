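#' Canonical names of the 107-feature set
#'
#' The canonical order is first-order (18), 3D shape (14), GLCM (24),
#' GLRLM (16), GLSZM (16), NGTDM (5), GLDM (14), each prefixed with its
#' family as `family/Feature`.
#'
#' @return Character vector of length 107.
#' @export
feature_names <- function() {
  c(paste0("firstorder/", firstorder_feature_names),
    paste0("shape/", shape_feature_names),
    paste0("glcm/", glcm_feature_names),
    paste0("glrlm/", glrlm_feature_names),
    paste0("glszm/", glszm_feature_names),
    paste0("ngtdm/", ngtdm_feature_names),
    paste0("gldm/", gldm_feature_names))
}

#' Extract the full 107-feature vector for one VOI
#'
#' Runs all seven feature families on a volume + mask pair and returns
#' the canonical, ordered 107-entry feature vector. All values are
#' guaranteed finite: degenerate inputs (constant, single-voxel or
#' single-gray-level VOIs) produce the documented conventional values
#' rather than NaN.
#'
#' @param volume A [volume3d()].
#' @param mask A [voi_mask()] on the same grid.
#' @param scheme A [discretization_scheme()].
#' @param glcm_distance GLCM offset distance in voxels (default 1).
#' @param gldm_alpha GLDM dependence threshold (default 0).
#' @param shape Optional precomputed [shape3d_features()] row; the mask
#'   does not change across the frames of a dynamic series, so per-frame
#'   extraction reuses one shape computation.
#' @return A 1-row tibble with exactly 107 finite columns in canonical
#'   order.
#' @export
extract_features <- function(volume, mask, scheme = discretization_scheme(),
                             glcm_distance = 1, gldm_alpha = 0,
                             shape = NULL) {
  check_same_grid(volume, mask)
  # crop both to the mask bounding box: features depend only on in-mask
  # voxels and their neighborhood structure
  vol_c <- volume3d(crop_to_bbox(volume$data, mask$data), volume$spacing)
  mask_c <- voi_mask(crop_to_bbox(mask$data, mask$data), mask$spacing)

  fo <- with_family_context("firstorder",
                            first_order_features(vol_c, mask_c, scheme))
  sh <- shape %||% with_family_context("shape", shape3d_features(mask_c))
  qv <- discretize(vol_c, mask_c, scheme)
  out <- dplyr::bind_cols(
    fo, sh,
    with_family_context("glcm", glcm_features(qv, glcm_distance)),
    with_family_context("glrlm", glrlm_features(qv)),
    with_family_context("glszm", glszm_features(qv)),
    with_family_context("ngtdm", ngtdm_features(qv)),
    with_family_context("gldm", gldm_features(qv, gldm_alpha)))
  stopifnot(identical(names(out), feature_names()))
  bad <- !vapply(out, is.finite, logical(1))
  if (any(bad)) {
    stop_dynomics(paste0("non-finite feature values: ",
                         paste(names(out)[bad], collapse = ", ")),
                  class = "dynomics_feature_error")
  }
  attr(out, "settings") <- list(
    discretization = unclass(scheme), glcm_distance = glcm_distance,
    gldm_alpha = gldm_alpha)
  out
}

# re-raise family errors with the family named, so a failing frame or
# family is identifiable from the condition message
with_family_context <- function(family, expr) {
  tryCatch(expr, error = function(e) {
    stop_dynomics(paste0("feature family '", family, "' failed: ",
                         conditionMessage(e)),
                  class = "dynomics_feature_error")
  })
}

#' Write / read a feature table as CSV with a JSON settings sidecar
#'
#' The CSV holds one row per sample with the canonical feature names as
#' header; extraction settings (discretization, distances, alpha) are
#' recorded alongside in `<path>.settings.json` for provenance.
#'
#' @param features A tibble of features (e.g. from [extract_features()]).
#' @param path Output CSV path.
#' @param settings Optional settings list; defaults to the tibble's
#'   `settings` attribute.
#' @return `path` invisibly (`write`), or a tibble (`read`).
#' @export
write_feature_table <- function(features, path, settings = NULL) {
  readr::write_csv(features, path)
  settings <- settings %||% attr(features, "settings")
  if (!is.null(settings)) {
    jsonlite::write_json(settings, paste0(path, ".settings.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".settings.json")
  if (file.exists(sidecar)) {
    attr(out, "settings") <- jsonlite::read_json(sidecar)
  }
  out
}
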