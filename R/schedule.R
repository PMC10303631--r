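#' Frame schedule of a dynamic acquisition
#'
#' A frame schedule lists the start time and duration (both in seconds) of
#' every timeframe of a dynamic PET acquisition. Frames must be sorted,
#' non-overlapping, and have positive durations.
#'
#' @param start_s Numeric vector of frame start times in seconds.
#' @param duration_s Numeric vector of frame durations in seconds.
#' @return A tibble of class `frame_schedule` with columns `start_s` and
#'   `duration_s`.
#' @examples
#' frame_schedule(c(0, 5, 10), c(5, 5, 10))
#' @export
frame_schedule <- function(start_s, duration_s) {
  if (length(start_s) != length(duration_s) || length(start_s) < 1) {
    stop_dynomics("`start_s` and `duration_s` must have equal length >= 1",
                  class = "dynomics_schedule_error")
  }
  if (!all(is.finite(start_s)) || !all(is.finite(duration_s))) {
    stop_dynomics("frame times must be finite",
                  class = "dynomics_schedule_error")
  }
  if (any(duration_s <= 0)) {
    stop_dynomics("frame durations must be positive",
                  class = "dynomics_schedule_error")
  }
  if (is.unsorted(start_s, strictly = TRUE) && length(start_s) > 1) {
    stop_dynomics("frames must be sorted by start time",
                  class = "dynomics_schedule_error")
  }
  ends <- start_s + duration_s
  if (length(start_s) > 1 &&
      any(start_s[-1] < ends[-length(ends)] - 1e-9)) {
    stop_dynomics("frames must not overlap",
                  class = "dynomics_schedule_error")
  }
  out <- tibble(start_s = as.numeric(start_s),
                duration_s = as.numeric(duration_s))
  class(out) <- c("frame_schedule", class(out))
  out
}

#' Default dynamic PET frame schedule
#'
#' The breast dynamic FLT-PET protocol schedule: 16 frames of 5 s, 7 of
#' 10 s, 5 of 30 s, 5 of 60 s, 5 of 180 s and 6 of 300 s (44 frames,
#' 3220 s total).
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  durations <- c(rep(5, 16), rep(10, 7), rep(30, 5), rep(60, 5),
                 rep(180, 5), rep(300, 6))
  frame_schedule(start_s = cumsum(c(0, durations[-length(durations)])),
                 duration_s = durations)
}

#' Frame midpoints of a schedule
#'
#' @param schedule A [frame_schedule()].
#' @return Numeric vector of frame midpoints in seconds.
#' @export
frame_midpoints <- function(schedule) {
  schedule$start_s + schedule$duration_s / 2
}

#' Read / write a frame schedule CSV
#'
#' The CSV dialect is a UTF-8 comma-separated file with header
#' `start_s,duration_s`.
#'
#' @param path File path.
#' @param schedule A [frame_schedule()].
#' @return `read_frame_schedule()` returns a [frame_schedule()];
#'   `write_frame_schedule()` returns `path` invisibly.
#' @export
read_frame_schedule <- function(path) {
  if (!file.exists(path)) {
    stop_dynomics(paste0("schedule file not found: ", path),
                  class = "dynomics_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("start_s", "duration_s") %in% names(df))) {
    stop_dynomics("schedule CSV must have columns start_s, duration_s",
                  class = "dynomics_io_error")
  }
  frame_schedule(df$start_s, df$duration_s)
}

#' @rdname read_frame_schedule
#' @export
write_frame_schedule <- function(schedule, path) {
  readr::write_csv(tibble(start_s = schedule$start_s,
                          duration_s = schedule$duration_s), path)
  invisible(path)
}
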