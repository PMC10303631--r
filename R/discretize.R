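#' Gray-level discretization scheme
#'
#' Texture families operate on gray levels obtained by discretizing the
#' in-mask intensities, either into a fixed number of bins spanning the
#' in-mask range (`fixed_bin_count`, the default, robust to the per-frame
#' intensity-range changes of dynamic series) or into bins of fixed
#' intensity width (`fixed_bin_width`).
#'
#' @param mode `"fixed_bin_count"` or `"fixed_bin_width"`.
#' @param n_bins Number of gray levels for `fixed_bin_count` (default 32).
#' @param bin_width Bin width in intensity units for `fixed_bin_width`.
#' @return An object of class `discretization_scheme`.
#' @export
discretization_scheme <- function(mode = c("fixed_bin_count",
                                           "fixed_bin_width"),
                                  n_bins = 32, bin_width = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed_bin_count") {
    if (!is.numeric(n_bins) || n_bins < 2) {
      stop_dynomics("`n_bins` must be >= 2", class = "dynomics_type_error")
    }
  } else {
    if (is.null(bin_width) || !is.numeric(bin_width) || bin_width <= 0) {
      stop_dynomics("`bin_width` must be > 0", class = "dynomics_type_error")
    }
  }
  structure(list(mode = mode, n_bins = as.integer(n_bins),
                 bin_width = bin_width),
            class = "discretization_scheme")
}

#' Discretize a volume of interest into gray levels
#'
#' Under `fixed_bin_count`, in-mask value `x` maps to
#' `1 + floor(Ng * (x - min) / (max - min))`, clipped to `Ng`; a constant
#' region maps to a single level (`Ng = 1`). Under `fixed_bin_width`, `x`
#' maps to `floor(x / width) - floor(min / width) + 1`.
#'
#' @param volume A [volume3d()].
#' @param mask A [voi_mask()] on the same grid.
#' @param scheme A [discretization_scheme()].
#' @return An object of class `quantized_voi`: integer level grid (0
#'   outside the mask), `ng` gray levels, mask and spacing.
#' @export
discretize <- function(volume, mask, scheme = discretization_scheme()) {
  check_same_grid(volume, mask)
  x <- volume$data[mask$data]
  if (!all(is.finite(x))) {
    stop_dynomics("non-finite in-mask intensities",
                  class = "dynomics_type_error")
  }
  if (scheme$mode == "fixed_bin_count") {
    rng <- range(x)
    if (rng[2] - rng[1] <= 0) {
      lev_in <- rep(1L, length(x))
      ng <- 1L
    } else {
      ng <- scheme$n_bins
      lev_in <- pmin(1L + as.integer(floor(
        ng * (x - rng[1]) / (rng[2] - rng[1]))), ng)
    }
  } else {
    w <- scheme$bin_width
    lev_in <- as.integer(floor(x / w) - floor(min(x) / w) + 1)
    ng <- max(lev_in)
  }
  levels <- array(0L, dim(mask$data))
  levels[mask$data] <- lev_in
  structure(list(levels = levels, ng = as.integer(ng), mask = mask,
                 spacing = mask$spacing),
            class = "quantized_voi")
}

#' @export
print.quantized_voi <- function(x, ...) {
  cat(sprintf("<quantized_voi> %s grid, %d voxels, Ng = %d\n",
              paste(dim(x$levels), collapse = "x"), sum(x$mask$data), x$ng))
  invisible(x)
}

# crop a quantized VOI (or volume+mask pair) to the mask bounding box;
# texture kernels scan the whole array, so this is a pure speed measure
crop_to_bbox <- function(arr, mask_data) {
  idx <- which(mask_data, arr.ind = TRUE)
  rx <- range(idx[, 1]); ry <- range(idx[, 2]); rz <- range(idx[, 3])
  arr[rx[1]:rx[2], ry[1]:ry[2], rz[1]:rz[2], drop = FALSE]
}
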