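#' 3D scalar volume
#'
#' A 3D scalar grid (activity concentration in kBq/mL or SUV) with voxel
#' spacing and origin in millimetres.
#'
#' @param data 3D numeric array.
#' @param spacing Voxel spacing in mm, length-3 positive numeric.
#' @param origin Grid origin in mm, length-3 numeric.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop_dynomics("`data` must be a 3D array", class = "dynomics_type_error")
  }
  if (!all(is.finite(data))) {
    stop_dynomics("volume contains non-finite voxels",
                  class = "dynomics_type_error")
  }
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_dynomics("`spacing` must be 3 positive values",
                  class = "dynomics_type_error")
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "volume3d")
}

#' Binary volume-of-interest mask
#'
#' @param data 3D logical (or 0/1) array; must contain at least one
#'   foreground voxel.
#' @param spacing Voxel spacing in mm.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop_dynomics("`data` must be a 3D array", class = "dynomics_type_error")
  }
  m <- array(as.logical(data), dim(data))
  if (anyNA(m)) {
    stop_dynomics("mask contains missing values", class = "dynomics_type_error")
  }
  if (!any(m)) {
    stop_dynomics("mask has no foreground voxels",
                  class = "dynomics_type_error")
  }
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop_dynomics("`spacing` must be 3 positive values",
                  class = "dynomics_type_error")
  }
  structure(list(data = m, spacing = as.numeric(spacing)),
            class = "voi_mask")
}

#' Dynamic (4D) PET series
#'
#' An ordered stack of 3D volumes, one per timeframe, together with its
#' frame schedule and intensity units.
#'
#' @param data 4D numeric array (x, y, z, frame).
#' @param schedule A [frame_schedule()] whose length equals the 4th
#'   dimension of `data`.
#' @param spacing Voxel spacing in mm.
#' @param units `"concentration"` (kBq/mL) or `"SUV"`.
#' @param origin Grid origin in mm.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(data, schedule, spacing = c(1, 1, 1),
                           units = c("concentration", "SUV"),
                           origin = c(0, 0, 0)) {
  units <- match.arg(units)
  if (!is.array(data) || length(dim(data)) != 4) {
    stop_dynomics("`data` must be a 4D array", class = "dynomics_type_error")
  }
  if (!inherits(schedule, "frame_schedule")) {
    stop_dynomics("`schedule` must be a frame_schedule",
                  class = "dynomics_type_error")
  }
  if (dim(data)[4] != nrow(schedule)) {
    stop_dynomics(sprintf(
      "frame-count mismatch: series has %d frames, schedule has %d rows",
      dim(data)[4], nrow(schedule)), class = "dynomics_frame_mismatch")
  }
  if (!all(is.finite(data))) {
    stop_dynomics("series contains non-finite voxels",
                  class = "dynomics_type_error")
  }
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop_dynomics("`spacing` must be 3 positive values",
                  class = "dynomics_type_error")
  }
  structure(list(data = data, schedule = schedule,
                 spacing = as.numeric(spacing), units = units,
                 origin = as.numeric(origin)),
            class = "dynamic_series")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels, spacing (%s) mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", ")))
  invisible(x)
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %s grid, %d foreground voxels\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' @export
print.dynamic_series <- function(x, ...) {
  cat(sprintf("<dynamic_series> %s voxels x %d frames [%s], spacing (%s) mm\n",
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4],
              x$units, paste(format(x$spacing), collapse = ", ")))
  invisible(x)
}

#' Number of frames in a dynamic series
#' @param series A [dynamic_series()].
#' @return Integer frame count.
#' @export
n_frames <- function(series) {
  dim(series$data)[4]
}

#' Extract one frame of a dynamic series as a volume
#' @param series A [dynamic_series()].
#' @param frame Frame index (1-based).
#' @return A [volume3d()].
#' @export
get_frame <- function(series, frame) {
  nf <- n_frames(series)
  if (frame < 1 || frame > nf) {
    stop_dynomics(sprintf("frame %d out of range [1, %d]", frame, nf),
                  class = "dynomics_type_error")
  }
  volume3d(series$data[, , , frame, drop = TRUE], series$spacing,
           series$origin)
}

check_same_grid <- function(volume, mask) {
  if (!identical(dim(volume$data)[1:3], dim(mask$data))) {
    stop_dynomics(sprintf(
      "volume grid (%s) and mask grid (%s) differ",
      paste(dim(volume$data)[1:3], collapse = "x"),
      paste(dim(mask$data), collapse = "x")),
      class = "dynomics_grid_mismatch")
  }
  invisible(TRUE)
}
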