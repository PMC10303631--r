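# plain numeric array from a niftiImage (drop image-header attributes)
strip_nifti_attrs <- function(img) {
  array(as.numeric(img), dim = dim(img))
}

#' Read a 4D dynamic PET series from NIfTI + schedule CSV
#'
#' The NIfTI file must be 4D and its 4th dimension must match the number
#' of rows of the schedule; a mismatch is an error, never a truncation.
#'
#' @param volume_path Path to a 4D NIfTI-1 file (.nii or .nii.gz).
#' @param schedule_path Path to a schedule CSV (`start_s,duration_s`).
#' @param units Intensity units of the stored voxels, `"concentration"`
#'   (kBq/mL, the default) or `"SUV"`.
#' @return A [dynamic_series()].
#' @export
read_dynamic_series <- function(volume_path, schedule_path,
                                units = c("concentration", "SUV")) {
  units <- match.arg(units)
  if (!file.exists(volume_path)) {
    stop_dynomics(paste0("volume file not found: ", volume_path),
                  class = "dynomics_io_error")
  }
  img <- RNifti::readNifti(volume_path)
  arr <- strip_nifti_attrs(img)
  if (length(dim(arr)) != 4) {
    stop_dynomics(sprintf("expected a 4D NIfTI, got %d dimensions",
                          length(dim(arr))), class = "dynomics_io_error")
  }
  schedule <- read_frame_schedule(schedule_path)
  spacing <- abs(RNifti::pixdim(img))[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) spacing <- c(1, 1, 1)
  dynamic_series(arr, schedule, spacing = spacing, units = units)
}

#' Write a dynamic series to NIfTI (+ optional schedule CSV)
#'
#' @param series A [dynamic_series()].
#' @param volume_path Output NIfTI path.
#' @param schedule_path Optional output schedule CSV path.
#' @return `volume_path`, invisibly.
#' @export
write_dynamic_series <- function(series, volume_path, schedule_path = NULL) {
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$spacing, 1)
  RNifti::writeNifti(img, volume_path, datatype = "double")
  if (!is.null(schedule_path)) write_frame_schedule(series$schedule,
                                                    schedule_path)
  invisible(volume_path)
}

#' Read / write a 3D volume or binary mask from NIfTI
#'
#' @param path NIfTI file path.
#' @param volume A [volume3d()].
#' @param mask A [voi_mask()].
#' @return `read_volume()` a [volume3d()]; `read_mask()` a [voi_mask()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop_dynomics(paste0("file not found: ", path),
                  class = "dynomics_io_error")
  }
  img <- RNifti::readNifti(path)
  arr <- strip_nifti_attrs(img)
  if (length(dim(arr)) != 3) {
    stop_dynomics("expected a 3D NIfTI", class = "dynomics_io_error")
  }
  spacing <- abs(RNifti::pixdim(img))[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) spacing <- c(1, 1, 1)
  volume3d(arr, spacing = spacing)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  voi_mask(v$data != 0, spacing = v$spacing)
}

#' @rdname read_volume
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Normalize an activity-concentration series to SUV
#'
#' Body-weight standardized uptake value:
#' `SUV = C[kBq/mL] * weight[g] / dose[kBq]`, assuming a tissue density of
#' 1 g/mL, which reduces to `C * weight_kg / dose_MBq` because the two
#' factor-1000 unit conversions cancel. Decay correction is assumed to be
#' applied at reconstruction; no decay term is included.
#'
#' @param series A [dynamic_series()] in concentration units.
#' @param dose_MBq Injected dose in MBq (> 0).
#' @param weight_kg Patient body weight in kg (> 0).
#' @return A [dynamic_series()] in SUV units.
#' @export
suv_normalize <- function(series, dose_MBq, weight_kg) {
  if (!inherits(series, "dynamic_series")) {
    stop_dynomics("`series` must be a dynamic_series",
                  class = "dynomics_type_error")
  }
  if (series$units == "SUV") {
    stop_dynomics("series is already in SUV units",
                  class = "dynomics_units_error")
  }
  if (!is.finite(dose_MBq) || dose_MBq <= 0) {
    stop_dynomics("`dose_MBq` must be positive",
                  class = "dynomics_units_error")
  }
  if (!is.finite(weight_kg) || weight_kg <= 0) {
    stop_dynomics("`weight_kg` must be positive",
                  class = "dynomics_units_error")
  }
  # kBq/mL * (kg * 1000 g/kg) / (MBq * 1000 kBq/MBq) = unitless SUV
  out <- series
  out$data <- series$data * (weight_kg / dose_MBq)
  out$units <- "SUV"
  out
}

#' Static image as the mean of the last k frames
#'
#' The static PET image is the voxelwise arithmetic mean of the final `k`
#' timeframes of the dynamic acquisition (default 5).
#'
#' @param series A [dynamic_series()].
#' @param k Number of trailing frames to average (default 5).
#' @return A [volume3d()].
#' @export
make_static_image <- function(series, k = 5) {
  nf <- n_frames(series)
  if (k < 1 || k > nf) {
    stop_dynomics(sprintf("`k` must be in [1, %d], got %s", nf, k),
                  class = "dynomics_type_error")
  }
  idx <- seq(nf - k + 1, nf)
  dat <- series$data[, , , idx, drop = FALSE]
  volume3d(apply(dat, 1:3, mean), series$spacing, series$origin)
}

#' Mirror a lesion mask into a contralateral reference mask
#'
#' Reflects the mask across the mid-sagittal plane of the image grid
#' (left-right axis, by default the first array axis), then applies an
#' optional integer voxel translation. The mirrored mask must stay fully
#' inside the grid.
#'
#' @param mask A [voi_mask()].
#' @param offset_vox Integer length-3 translation in voxels (default 0).
#' @param axis Grid axis treated as left-right (default 1).
#' @return A [voi_mask()] with the same foreground voxel count.
#' @export
mirror_reference_mask <- function(mask, offset_vox = c(0, 0, 0), axis = 1) {
  if (!inherits(mask, "voi_mask")) {
    stop_dynomics("`mask` must be a voi_mask", class = "dynomics_type_error")
  }
  if (!axis %in% 1:3) {
    stop_dynomics("`axis` must be 1, 2 or 3", class = "dynomics_type_error")
  }
  offset_vox <- as.integer(round(offset_vox))
  dm <- dim(mask$data)
  idx <- which(mask$data, arr.ind = TRUE)
  # reflect: index i -> W + 1 - i on the chosen axis (1-based)
  idx[, axis] <- dm[axis] + 1L - idx[, axis]
  idx <- sweep(idx, 2, offset_vox, "+")
  out_of_grid <- idx[, 1] < 1 | idx[, 1] > dm[1] |
    idx[, 2] < 1 | idx[, 2] > dm[2] |
    idx[, 3] < 1 | idx[, 3] > dm[3]
  if (any(out_of_grid)) {
    stop_dynomics(sprintf(
      "mirrored mask exits the grid: %d voxel(s) clipped",
      sum(out_of_grid)), class = "dynomics_mask_error")
  }
  m <- array(FALSE, dm)
  m[idx] <- TRUE
  voi_mask(m, mask$spacing)
}
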